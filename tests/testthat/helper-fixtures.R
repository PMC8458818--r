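# Shared, lazily built fixtures.  The three reduced-lattice joint fits and
# the fusion recovery fit are expensive, so they are built once per test
# run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# the frozen synthetic suite (deterministic)
fx_suite <- function() memo("suite", function() gen_marginal_suite(seed = 1))

# one reduced-lattice (N = 9) joint fit per outcome, acceptance profile
fx_joint <- function(outcome) {
  memo(paste0("joint_", outcome), function() {
    suite <- fx_suite()
    mg <- c(suite$marginals[outcome],
            suite$marginals[c("stress", "sleep", "exertion")])
    fit_joint_density(mg, default_effect_sizes(), outcome = outcome,
                      n_per_axis = 9L)
  })
}

# a tiny N = 3 model from an exactly representable problem, for
# conditional-density and slice tests
fx_small_model <- function() {
  memo("small_model", function() {
    b <- build_basis(3, c(0.1, 0.2))
    gr <- gen_representable_joint(b, nnz = 6, seed = 3)
    m <- adaptive_sparsify(gr$system, lam = 1e-8, target_nnz = 20)
    m$transforms <- rep(list(NULL), 4)
    m$variables <- c("y", "x1", "x2", "x3")
    m
  })
}

# fusion parameter-recovery fit: 4 sources x 2000 draws from a known truth
fx_fusion_recovery <- function() {
  memo("fusion_recovery", function() {
    truth <- default_fusion_truth()
    sources <- gen_fusion_sources(truth, sizes = rep(2000L, 4), seed = 7)
    list(truth = truth, sources = sources,
         fit = fit_latent_fusion(sources))
  })
}

# L1 distance between a fitted latent density and the truth mixture mapped
# onto the fitted (anchored) scale
fusion_l1_vs_truth <- function(truth, fit, lo = -8, hi = 12, n = 4001) {
  a1 <- truth$source_models[[1]]$a; b1 <- truth$source_models[[1]]$b
  ah <- fit$source_models[[1]]$a;   bh <- fit$source_models[[1]]$b
  g <- seq(lo, hi, length.out = n)
  s <- (ah * g + bh - b1) / a1
  dtruth <- perfdens:::mixture_density(truth$mixture, s) * abs(ah / a1)
  dfit <- perfdens:::mixture_density(fit$mixture, g)
  perfdens:::trapz(g, abs(dtruth - dfit))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
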