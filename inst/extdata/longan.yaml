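num_classes: 1
widths:
- 32
- 64
- 128
- 256
- 512
depths:
- 1
- 2
- 2
- 1
use_dense: yes
use_faster: yes
use_vov: yes
box_loss: inner_siou
dense:
  in_channels: 32
  growth_rate: 16
  num_layers: 3
  bottleneck_factor: 3
  out_channels: 64
siou:
  ratio: 1.0
  theta: 4.0
  eps: 1.0e-09
partial_ratio: 0.25
reg_max: 16
strides:
- 8
- 16
- 32
img_size:
- 640
- 640
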