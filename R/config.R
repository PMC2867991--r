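#' Analysis configuration
#'
#' Bundle of the tunable parameters used across the pipeline. Defaults follow
#' the conditions this pipeline targets: delay `tau = 3` samples and embedding dimension
#' `m = 16` for the single-lead reconstructions, approximate-entropy pattern
#' length `m = 2` with tolerance `0.2 * SD`, alpha (8-13 Hz) and beta
#' (14-30 Hz) band limits, and an 8 x 6 competitive layer for the SOM.
#'
#' @param tau delay in samples for delay embeddings (>= 1).
#' @param m_embed embedding dimension (>= 2).
#' @param apen_m approximate-entropy pattern length (>= 1).
#' @param apen_r_factor ApEn tolerance as a multiple of the series SD.
#' @param theiler_w Theiler window in samples, or `NULL` to derive it from
#'   the mean period for delay embeddings (0 for multi-lead embeddings).
#' @param ctm_radius_factor SODP radius as a multiple of the SD of SODP
#'   point norms.
#' @param n_surrogates number of IAAFT surrogates in the determinism test.
#' @param surrogate_iters IAAFT iterations per surrogate.
#' @param ar_order_max upper bound of the AIC order search.
#' @param bands named list of `c(low, high)` frequency bands in Hz.
#' @param som_rows,som_cols SOM grid shape.
#' @param som_epochs SOM training epochs.
#' @param n_points maximum number of samples used per series for the
#'   correlation-dimension estimate (trajectories are truncated to this
#'   length before pair counting).
#' @param seed integer RNG seed for all stochastic components.
#' @return A validated list of class `"AnalysisConfig"`.
#' @examples
#' cfg <- analysisConfig(seed = 7)
#' cfg$tau
#' @export
analysisConfig <- function(tau = 3L, m_embed = 16L, apen_m = 2L,
                           apen_r_factor = 0.2, theiler_w = NULL,
                           ctm_radius_factor = 1.0, n_surrogates = 19L,
                           surrogate_iters = 100L, ar_order_max = 64L,
                           bands = list(alpha = c(8, 13), beta = c(14, 30)),
                           som_rows = 8L, som_cols = 6L, som_epochs = 500L,
                           n_points = 2000L, seed = 1L) {
  cfg <- list(tau = as.integer(tau), m_embed = as.integer(m_embed),
              apen_m = as.integer(apen_m), apen_r_factor = apen_r_factor,
              theiler_w = if (is.null(theiler_w)) NULL else
                as.integer(theiler_w),
              ctm_radius_factor = ctm_radius_factor,
              n_surrogates = as.integer(n_surrogates),
              surrogate_iters = as.integer(surrogate_iters),
              ar_order_max = as.integer(ar_order_max), bands = bands,
              som_rows = as.integer(som_rows), som_cols = as.integer(som_cols),
              som_epochs = as.integer(som_epochs),
              n_points = as.integer(n_points), seed = as.integer(seed))
  class(cfg) <- "AnalysisConfig"
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  stopifnot(cfg$tau >= 1L, cfg$m_embed >= 2L, cfg$apen_m >= 1L,
            cfg$apen_r_factor > 0, cfg$ctm_radius_factor > 0,
            cfg$n_surrogates >= 1L, cfg$surrogate_iters >= 1L,
            cfg$som_rows >= 1L, cfg$som_cols >= 1L, cfg$n_points >= 16L)
  for (b in cfg$bands)
    stopifnot(length(b) == 2L, b[1] >= 0, b[2] > b[1])
  invisible(cfg)
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig\n")
  cat(sprintf("  embedding: tau = %d, m = %d\n", x$tau, x$m_embed))
  cat(sprintf("  ApEn: m = %d, r = %g * SD\n", x$apen_m, x$apen_r_factor))
  cat(sprintf("  surrogates: %d x %d IAAFT iterations\n",
              x$n_surrogates, x$surrogate_iters))
  cat(sprintf("  SOM: %d x %d, %d epochs; seed %d\n",
              x$som_rows, x$som_cols, x$som_epochs, x$seed))
  invisible(x)
}

#' Read / write an AnalysisConfig as YAML
#'
#' The YAML keys mirror the [analysisConfig()] argument names; absent keys
#' keep their defaults.
#'
#' @param path file path.
#' @return `readAnalysisConfig` returns an `AnalysisConfig`;
#'   `writeAnalysisConfig` returns the path, invisibly.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$bands))
    vals$bands <- lapply(vals$bands, as.numeric)
  do.call(analysisConfig, vals)
}

#' @rdname readAnalysisConfig
#' @param cfg an `AnalysisConfig`.
#' @export
writeAnalysisConfig <- function(cfg, path) {
  vals <- unclass(cfg)
  vals$bands <- lapply(vals$bands, as.numeric)
  yaml::write_yaml(vals, path)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# user-level reproducibility.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from a parent seed, kept inside 32-bit
# integer range.
deriveSeeds <- function(seed, n) {
  as.integer((as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483587) + 1L
}
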