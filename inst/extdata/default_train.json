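{
  "comment": "spline control points of the shipped default train; produced by optimize_train() at the CRB reference parameters (seed 20260910, n_control 8, maxiter 40, restarts 2)",
  "alpha_ctrl": [0.461420889922362, 0.371989303127246, 0.001, 1.42815913135656, 0.549408020706913, 3.14159265358979, 0.0523451284422938, 0.001],
  "trf_ctrl": [0.000857814248473224, 0.00081235640981836, 0.000642031310945425, 0.0001, 0.000765596907640229, 0.000377761509264971, 0.000319976571478156, 0.000407196614735493],
  "trf_inv": 0.0005,
  "trf_min": 0.0001,
  "trf_max": 0.001,
  "objective_s": 5371.00178756903,
  "objective_init_s": 1000000000000
}
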