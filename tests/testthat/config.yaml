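model:
  variant: one_comp_active_if
  soma:
    C_soma: 24.0
    g_leak_soma: 48.0
    g_klva_bar: 192.0
    E_L: -60.0
    E_K: -75.0
    E_syn: 0.0
  generator:
    I_const: 200.0
    A1: 3500.0
    A2: 3000.0
    tau1: 0.02
    tau2: 0.2
    V_theta: -58.299999999999997
    T_ref: 0.9
  kinetics:
    Q10: 2.5
    T0: 23.0
    T1: 40.0
    q10_convention: speedup
input:
  f_stim: 4000.0
  lambda0: 500.0
  r: 0.6
  M: 150
  H_alpha: 1.3
  W_alpha: 0.1
  delta: 0.0
integration:
  dt_us: 10.0
  duration_ms: 1000.0
  warmup_ms: 20.0
seed: 1
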