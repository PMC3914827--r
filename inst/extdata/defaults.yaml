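# Default parameters for all agents and experiment drivers. Every unprinted
# tunable of the model is visible and overridable here.
agents:
  # Own volatility prior: assumed random-walk variance of the hidden states
  # the agent tracks (log scale; sigma = exp(log_sigma)). Sets the effective
  # learning rate of every Bayesian phenotype.
  log_sigma: -1.0
  # Softmax exploration temperature, shared by all phenotypes.
  beta: 0.1
  # Rescorla-Wagner learning rate of the RL phenotype.
  rl_alpha: 0.1
  # Gaussian prior moments on the simulated opponent's hidden parameters
  # (log-volatility, log-temperature), used by every k-ToM level.
  theta_prior:
    mean: [0.0, 0.0]
    variance: [1.0, 1.0]
  # k-ToM prior over candidate opponent levels: uniform unless overridden.
tournament:
  tau: 512
  n_reps: 500
  seed: 1
egt:
  omega_grid: [0.0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0]
  tau_grid: [1, 2, 4, 8, 16, 32, 64, 128, 256, 512]
  n_init: 128
  dt: 0.01
  t_max: 10000.0
  tol: 1.0e-8
  # equilibrium frequencies below this are reported as extinctions
  extinction_threshold: 1.0e-3
  # endpoints closer than this (max-norm) count as the same equilibrium
  uniqueness_tol: 1.0e-3
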