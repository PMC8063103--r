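{
  "GCaL": 1,
  "GCaT": 1,
  "GNa": 1,
  "Gto1": 1,
  "GKr": 1,
  "GKs": 1,
  "GK1": 1,
  "GCab": 1,
  "GNab": 1,
  "GClb": 1,
  "ImaxNCX": 1,
  "ImaxNaK": 1,
  "ICaP_max": 1,
  "Jmaxup": 0.0053,
  "RyR_P": [0.2, 0.22, 1, 1, 1, 8e-05, 1, 1, 1, 1, 1, 0.007],
  "NRyRs": 198000,
  "Buff_factor": 1,
  "geometry": {
    "n_domains": 18,
    "membrane_domain_indices": [1, 18],
    "v_cyto": 3.88888888888889e-13,
    "v_sr": 2.33333333333333e-14,
    "v_srs": 7.77777777777778e-15,
    "v_sl": 7.77777777777778e-15,
    "v_junct": 3.88888888888889e-16,
    "diffusion_coupling": 0.8,
    "srs_coupling": 0.4
  }
}
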