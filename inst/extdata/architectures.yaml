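# Discriminator architecture table, version 1.
#
# Each named variant is an ordered layer list applied to a binary fingerprint
# (optionally concatenated with a one-hot condition vector). Every variant
# starts with a dense input projection to the fingerprint length, reshapes to
# a one-channel 1-D signal, and ends with a 2-unit dense output (class scores
# for real vs. generated, or active vs. inactive). The local-response
# normalisation of the original AlexNet/ZFNet is omitted; batch
# normalisation lives in the generator only, so the adversarial loop never
# lets the discriminator read batch statistics. The canonical image
# architectures are translated to 1-D kernels of the same extent; channel
# widths are scaled down for fingerprint-length inputs (the canonical widths
# were designed for 224x224x3 images).
#
# VGGNet13 is VGGNet16 with the layers tagged group "asterisk" removed;
# VGGNet11 additionally removes the layers tagged group "pound".
version: 1
input_projection: {kind: dense, units: 168, activation: relu}
architectures:
  LeNet5:
    - {kind: conv, filters: 6, kernel: 5, stride: 1, pad: 2, activation: relu}
    - {kind: pool, size: 2, stride: 2}
    - {kind: conv, filters: 16, kernel: 5, stride: 1, pad: 0, activation: relu}
    - {kind: pool, size: 2, stride: 2}
    - {kind: flatten}
    - {kind: dense, units: 120, activation: relu}
    - {kind: dense, units: 84, activation: relu}
    - {kind: dense, units: 2}
  AlexNet:
    - {kind: conv, filters: 8, kernel: 11, stride: 4, pad: 5, activation: relu}
    - {kind: pool, size: 3, stride: 2}
    - {kind: conv, filters: 16, kernel: 5, stride: 1, pad: 2, activation: relu}
    - {kind: pool, size: 3, stride: 2}
    - {kind: conv, filters: 24, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 24, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 16, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: pool, size: 3, stride: 2}
    - {kind: flatten}
    - {kind: dense, units: 64, activation: relu}
    - {kind: dense, units: 32, activation: relu}
    - {kind: dense, units: 2}
  ZFNet:
    - {kind: conv, filters: 8, kernel: 7, stride: 2, pad: 3, activation: relu}
    - {kind: pool, size: 3, stride: 2}
    - {kind: conv, filters: 16, kernel: 5, stride: 2, pad: 2, activation: relu}
    - {kind: pool, size: 3, stride: 2}
    - {kind: conv, filters: 24, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 24, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 16, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: pool, size: 3, stride: 2}
    - {kind: flatten}
    - {kind: dense, units: 64, activation: relu}
    - {kind: dense, units: 32, activation: relu}
    - {kind: dense, units: 2}
  VGGNet16:
    - {kind: conv, filters: 8, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 8, kernel: 3, stride: 1, pad: 1, activation: relu, group: pound}
    - {kind: pool, size: 2, stride: 2}
    - {kind: conv, filters: 16, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 16, kernel: 3, stride: 1, pad: 1, activation: relu, group: pound}
    - {kind: pool, size: 2, stride: 2}
    - {kind: conv, filters: 32, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 32, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 32, kernel: 3, stride: 1, pad: 1, activation: relu, group: asterisk}
    - {kind: pool, size: 2, stride: 2}
    - {kind: conv, filters: 64, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 64, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 64, kernel: 3, stride: 1, pad: 1, activation: relu, group: asterisk}
    - {kind: pool, size: 2, stride: 2}
    - {kind: conv, filters: 64, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 64, kernel: 3, stride: 1, pad: 1, activation: relu}
    - {kind: conv, filters: 64, kernel: 3, stride: 1, pad: 1, activation: relu, group: asterisk}
    - {kind: pool, size: 2, stride: 2}
    - {kind: flatten}
    - {kind: dense, units: 64, activation: relu}
    - {kind: dense, units: 32, activation: relu}
    - {kind: dense, units: 2}
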