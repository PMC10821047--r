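# Default experiment configuration (synthetic fixture values).
# The gauge coordinates are invented fixtures chosen so the standard test
# points fall inside/outside the triangular sensing area as on the real
# device; they are not measurements.
test_reps: 10
train_reps: 1
target_kg: 25
aug_frac: 0.05
aug_copies: 3
train_frac: 0.85
hidden_load: 5
hidden_loc: 10
max_epochs: 150
test_method: welch
alpha_level: 0.05
sim_params:
  linear_gain: [0.0020, 0.0022, 0.0018]
  quad_coeff: [-6.0e-7, -5.0e-7, -7.0e-7]
  crosstalk:
    - [1.00, 0.02, 0.02]
    - [0.02, 1.00, 0.02]
    - [0.02, 0.02, 1.00]
  noise_frac: 0.01
  noise_floor: 5.0e-5
layouts:
  medial:
    gauge_positions:
      - [0.0, 1.0]
      - [0.0, 4.0]
      - [2.0, 2.5]
    surface_polygon:
      - [-0.5, -0.5]
      - [3.0, -0.5]
      - [3.0, 6.0]
      - [-0.5, 6.0]
  lateral:
    gauge_positions:
      - [0.0, 2.0]
      - [1.5, 6.0]
      - [3.0, 2.5]
    surface_polygon:
      - [-0.5, -0.5]
      - [3.5, -0.5]
      - [3.5, 6.0]
      - [-0.5, 6.0]
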