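# Example model configuration for spinefem.
# Every block is optional; omitted values fall back to the package defaults
# (the reference adolescent case).

targets:
  PI: 61          # pelvic incidence, degrees
  SS: 52          # sacral slope, degrees
  slip_pct: 30    # Taillard slip percentage (Grade II)

patient:
  age: 14
  height_cm: 157.2
  weight_kg: 45.5

materials:        # per-region overrides of the default material library
  trabecular:
    E: 100        # MPa
    nu: 0.2
  nucleus:
    E: 1
    nu: 0.499
  ligament_all:
    spring_k: 20  # N/mm

loading:
  g: 9.81
  torsion_stiffness: 1000   # N.mm/rad at each acetabulum
  follower_tol: 1.0e-3      # rad
  follower_max_iter: 25

mesh:
  nx: 12
  ny: 12
  nz_body: 4
  nz_disc: 2
  nz_sacrum: 4
  include_ribs: false
  pars_lysis: true
  dome_height_mm: 3
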