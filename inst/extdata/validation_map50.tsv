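dataset	model	class	map50
reflectance	yolov5	SD	90.7
reflectance	yolov5	OT	91.3
reflectance	efficientdet_d0	SD	87.5
reflectance	efficientdet_d0	OT	88.2
transmittance	yolov5	SD	97.1
transmittance	yolov5	OT	96.2
transmittance	efficientdet_d0	SD	96.2
transmittance	efficientdet_d0	OT	92.9
combined	yolov5	SD	94.1
combined	yolov5	OT	92.7
combined	efficientdet_d0	SD	90.7
combined	efficientdet_d0	OT	87.3
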