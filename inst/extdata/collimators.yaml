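# Divergent multi-slit collimator library.
# Widths/spacings in micrometres, angles in degrees, thickness in mm.
# w3/beta/ctc2 are omitted for 3-slit geometries (entrance w1, exit w2).
A:
  n_slits: 5
  slit_height: 10
  w1: 400
  w2: 400
  w3: 425
  alpha: 0.595
  beta: 0.632
  ctc1: 1150
  ctc2: 1275
  thickness: 30
Ah:
  n_slits: 5
  slit_height: 5
  w1: 400
  w2: 400
  w3: 425
  alpha: 0.595
  beta: 0.632
  ctc1: 1150
  ctc2: 1275
  thickness: 30
A3s:
  n_slits: 3
  slit_height: 10
  w1: 400
  w2: 400
  alpha: 0.595
  ctc1: 1150
  thickness: 30
B:
  n_slits: 5
  slit_height: 10
  w1: 400
  w2: 409
  w3: 500
  alpha: 0.611
  beta: 0.744
  ctc1: 1900
  ctc2: 1875
  thickness: 30
C:
  n_slits: 3
  slit_height: 10
  w1: 400
  w2: 425
  alpha: 0.632
  ctc1: 2425
  thickness: 30
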