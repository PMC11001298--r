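# Shared fixtures, built lazily and cached for the whole test run (several
# suites reuse the same simulated sessions).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Anesthetized-style imaging session used for GI-slope parameter recovery:
# 50 units (25 per phenotype, preset slopes +0.89 / -0.59), 180 trials at
# intermittency 0.2 / 0.5 / 0.8, default (moderate) noise.
slope_recovery_fixture <- function() {
  fixture("slope_recovery", function() {
    cfg <- generator_config(seed = 11)
    gl <- gen_glomerulus_population(50, frac_cluster1 = 0.5, cfg)
    ses <- gen_session(cfg, glomeruli = gl,
                       trial_gammas = rep(c(0.2, 0.5, 0.8), each = 60))
    list(config = cfg, glomeruli = gl, session = ses,
         result = process_session(ses))
  })
}

# Two-population session sized like the reported dataset (37 + 191 units),
# stimuli spanning the 0.1-0.8 intermittency range for tuning profiles.
cluster_fixture <- function() {
  fixture("cluster", function() {
    cfg <- generator_config(seed = 5)
    gl <- gen_glomerulus_population(228, frac_cluster1 = 37 / 228, cfg)
    ses <- gen_session(cfg, glomeruli = gl,
                       trial_gammas = rep(seq(0.1, 0.8, by = 0.1), each = 3))
    list(config = cfg, glomeruli = gl, session = ses,
         result = process_session(ses))
  })
}

# Strongly separable decoding session: 25 diverse units, 120 trials with CS+
# and CS- intermittency bands well apart, so a linear readout of GI should
# approach perfect accuracy.
decode_fixture <- function() {
  fixture("decode", function() {
    cfg <- generator_config(seed = 7)
    gl <- gen_glomerulus_population(25, frac_cluster1 = 0.4, cfg,
                                    slope_sd = 0.25)
    gammas <- with_seed_test(1301, sample(c(rep(c(0.5, 0.6, 0.7, 0.8), each = 15),
                                            rep(c(0.05, 0.1), each = 30))))
    ses <- gen_session(cfg, glomeruli = gl, trial_gammas = gammas)
    res <- process_session(ses)
    gm <- gi_matrix(res)
    list(config = cfg, glomeruli = gl, session = ses, result = res,
         X = gm$X, labels = label_cs(gm$gamma), gamma = gm$gamma)
  })
}

# Small behavioral-only session (fast; used by behavior and sniff suites).
behavior_session_fixture <- function() {
  fixture("behavior_session", function() {
    cfg <- generator_config(seed = 21)
    gen_session(cfg)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# analytic 9 s trial-shaped square stimulus helpers
default_cfg <- generator_config()
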