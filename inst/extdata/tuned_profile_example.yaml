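# Example tuned fusion profile for a two-detector ensemble
# (a YOLO-family model fused with an RT-DETR-family model).
# These are illustrative optimizer outputs for one particular dataset and
# detector pair -- a template for the file `run_phase("report")` consumes
# via `params_file`, NOT package defaults. Tune your own with the
# `optimize` phase.
iou_thr: 0.3466
skip_box_thr: 0.0340
weights:
  yolov8l: 4.2111
  rtdetr_l: 2.9897
conf_mode: mean
rescale_by_model_count: false
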