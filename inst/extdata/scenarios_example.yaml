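# Example scenario-suite configuration (see read_scenario_config()).
# Units: g_max mol m-2 s-1; K_max mmol m-2 s-1 MPa-1; potentials MPa;
# vuln_slope mmol m-2 s-1 MPa-2; bucket_size mol m-2; dt hours.
environments:
  humid:
    t_air: 20
    rh: 0.786
  arid:
    t_air: 30
    rh: 0.295
soil:
  bucket_size: 2500
  psi_e: -0.002
  b: 6
plants:
  c3_reference:
    pathway: C3
    g_max: 0.32
    psi_gs50: -1.5
    c: 0.2
    K_max: 8
    vuln_slope: 2.22
  c4_reference:
    pathway: C4
    g_max: 0.16
    psi_gs50: -1.5
    c: 0.2
    K_max: 8
    vuln_slope: 2.22
    photosynthesis:
      Vpmax: 55
      Kp: 120
dt: 0.5
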