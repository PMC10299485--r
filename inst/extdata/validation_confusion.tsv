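dataset	model	actual	pred_sd	pred_ot
reflectance	yolov5	SD	2035	209
reflectance	yolov5	OT	26	278
reflectance	efficientdet_d0	SD	1964	280
reflectance	efficientdet_d0	OT	36	268
transmittance	yolov5	SD	2179	65
transmittance	yolov5	OT	12	292
transmittance	efficientdet_d0	SD	2103	141
transmittance	efficientdet_d0	OT	22	282
combined	yolov5	SD	4223	265
combined	yolov5	OT	57	551
combined	efficientdet_d0	SD	4089	399
combined	efficientdet_d0	OT	77	531
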