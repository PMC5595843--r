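# Default model configuration: the fixed-parameter block of the
# conductance-based hypercolumn model, the feature-grid sampling, and the
# spontaneous variance floor of the detection stage.
fixed_params:
  n_s: 6          # surrounding hypercolumns feeding the centre
  "n": 2          # contrast-response exponent (quoted: bare n is a
                  # YAML 1.1 boolean)
  A: 2            # first-layer maximum firing amplitude
  m: 1            # voltage-to-rate slope
  T: 1            # firing threshold
  I_c: 1          # centre excitatory strength
  v_e: 4.6666667  # excitatory reversal (14/3)
  v_i: -0.6666667 # inhibitory reversal (-2/3)
  sigma_sf: 1     # default SF tuning width, octaves
  tau: 10         # membrane time constant (dynamical checks only)
grids:
  orientation_spacing: 2  # degrees, one 180-degree period
  sf_range: [0.5, 64]     # c/d, quarter-octave sampling
r0_floor: 0.01            # spontaneous variance floor, detection stage
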