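#' Generate deterministic test fixtures
#'
#' Produces the small, fully synthetic inputs used by the test-suite and by
#' worked examples: (a) `"chains"` - a single neutral chain plus a small PEC
#' box (chains on a lattice); (b) `"ideal-reservoir"` - a reservoir
#' configuration at a stated pH and salt concentration; (c) `"dp-curve"` -
#' a synthetic pressure-composition table generated from known fit
#' parameters (a0, a1, a2) with optional Gaussian noise; (d) `"sk-curves"` -
#' three constructed structure-factor curves (flat ideal-gas, small-k
#' divergence, mid-k correlation peak) for the demixing classifier. The
#' same seed always produces identical files.
#'
#' @param kind one of `"chains"`, `"ideal-reservoir"`, `"dp-curve"`,
#'   `"sk-curves"`.
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param ... kind-specific overrides: `dp-curve` accepts `a0`, `a1`, `a2`,
#'   `noise_sd`, `phi`; `chains` accepts `n_chains_per_species`,
#'   `chain_length`, `target_phi`; `ideal-reservoir` accepts `pH`,
#'   `c_salt`, `c_acid`, `c_divalent`.
#' @return named character vector of the files written.
#' @export
generate_fixtures <- function(kind = c("chains", "ideal-reservoir",
                                       "dp-curve", "sk-curves"),
                              dir = tempdir(), seed = 1L, ...) {
  kind <- match.arg(kind)
  dots <- list(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  arg <- function(name, default)
    if (!is.null(dots[[name]])) dots[[name]] else default

  if (kind == "chains") {
    ncps <- arg("n_chains_per_species", 4L)
    clen <- arg("chain_length", 8L)
    phi <- arg("target_phi", 0.15)
    chain <- build_single_chain(32)
    run <- run_langevin(chain, langevin_params(steps = 200L),
                        sample_every = 200L)
    f1 <- file.path(dir, "single_chain.xyz")
    write_xyz(run$trajectory, f1)
    pec <- build_initial_pec(ncps, clen, phi, relax_steps = 200L,
                             ewald_accuracy = 1e-2)
    run2 <- run_langevin(pec, langevin_params(steps = 100L),
                         sample_every = 100L)
    f2 <- file.path(dir, "small_pec.xyz")
    write_xyz(run2$trajectory, f2)
    return(c(single_chain = f1, small_pec = f2))
  }

  if (kind == "ideal-reservoir") {
    cfg <- default_run_config("supernatant", seed = seed)
    cfg$reservoir$pH <- arg("pH", 7)
    cfg$reservoir$c_salt <- arg("c_salt", 0.15)
    cfg$reservoir$c_acid <- arg("c_acid", 0)
    cfg$reservoir$c_divalent <- arg("c_divalent", 0)
    f <- file.path(dir, "ideal_reservoir.yaml")
    write_config(cfg, f)
    return(c(config = f))
  }

  if (kind == "dp-curve") {
    a0 <- arg("a0", -2); a1 <- arg("a1", 0.4); a2 <- arg("a2", 0.02)
    noise <- arg("noise_sd", 0)
    phi <- arg("phi", seq(0.08, 0.26, length.out = 8))
    dP <- .dp_model(phi, a0, a1, a2) + stats::rnorm(length(phi), 0, noise)
    tab <- pressure_point(phi, dP, stderr = rep(max(noise, 1e-6),
                                                length(phi)))
    f <- file.path(dir, "dp_curve.tsv")
    write_tsv(tab, f)
    attr(f, "truth") <- c(a0 = a0, a1 = a1, a2 = a2)
    return(c(dp_curve = f))
  }

  # sk-curves: three canonical shapes on a shared k-grid
  k <- 2 * pi / 10 * (1:12)
  flat <- data.frame(k = k, S = rep(1, length(k)))
  rising <- data.frame(k = k, S = 1 + 4 * exp(-k / 0.8))
  midpeak <- data.frame(k = k, S = 1 + 2 * exp(-(k - k[6])^2 / 0.1) +
                          0.5 * exp(-k / 0.8))
  f1 <- file.path(dir, "sk_flat.tsv")
  f2 <- file.path(dir, "sk_smallk.tsv")
  f3 <- file.path(dir, "sk_midpeak.tsv")
  write_tsv(flat, f1); write_tsv(rising, f2); write_tsv(midpeak, f3)
  c(flat = f1, smallk = f2, midpeak = f3)
}
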