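#' Immune-optimizer parameters
#'
#' Bundles every constant of the clonal-selection engine. Defaults are the
#' thresholding configuration (popsize 20, maxgen 200); [ica_segment()]
#' overrides popsize/maxgen to its own defaults (30/300) when no parameter
#' set is supplied.
#'
#' @param popsize Population size (>= 2). Default 20.
#' @param maxgen Generation cap (>= 1). Default 200.
#' @param qc Crossover probability in \[0, 1\]. Default 0.6.
#' @param qm Mutation probability in \[0, 1\]. Default 0.06.
#' @param lambda Affinity constant for the concentration count; must lie in
#'   \[0.9, 1\]. Default 0.95.
#' @param k Concentration penalty exponent; must be negative. Default -0.8.
#' @param mc Number of candidate clones granted to the top-ranked antibody
#'   (<= popsize). Default 10.
#' @param stall_gens Consecutive generations without improvement of the
#'   memory-cell affinity after which the stall rule stops the run. Default 20.
#' @param j_tol Absolute threshold on |J1 - J*| for the clustering stop rule,
#'   where J1 is the first-generation elite objective and J* the current elite
#'   objective. `NULL` (default) means `1e-3 * J1`.
#' @param seed Integer RNG seed; a single RNG stream per run is derived from it.
#' @return An object of class `immune_params` (a validated list).
#' @export
immune_params <- function(popsize = 20L, maxgen = 200L, qc = 0.6, qm = 0.06,
                          lambda = 0.95, k = -0.8, mc = 10L,
                          stall_gens = 20L, j_tol = NULL, seed = 1L) {
  if (!is_count(popsize, 2L)) stop("`popsize` must be an integer >= 2", call. = FALSE)
  if (!is_count(maxgen, 1L)) stop("`maxgen` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(qc) || qc < 0 || qc > 1) stop("`qc` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(qm) || qm < 0 || qm > 1) stop("`qm` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(lambda) || lambda < 0.9 || lambda > 1) {
    stop("`lambda` must lie in [0.9, 1]", call. = FALSE)
  }
  if (!is.numeric(k) || k >= 0) stop("`k` must be negative", call. = FALSE)
  if (!is_count(mc, 1L) || mc > popsize) {
    stop("`mc` must be an integer in [1, popsize]", call. = FALSE)
  }
  if (!is_count(stall_gens, 1L)) stop("`stall_gens` must be an integer >= 1", call. = FALSE)
  if (!is.null(j_tol) && (!is.numeric(j_tol) || j_tol < 0)) {
    stop("`j_tol` must be NULL or a nonnegative number", call. = FALSE)
  }
  if (!is_count(seed, 0L)) stop("`seed` must be a nonnegative integer", call. = FALSE)
  structure(
    list(popsize = as.integer(popsize), maxgen = as.integer(maxgen),
         qc = qc, qm = qm, lambda = lambda, k = k, mc = as.integer(mc),
         stall_gens = as.integer(stall_gens), j_tol = j_tol,
         seed = as.integer(seed)),
    class = "immune_params"
  )
}

#' @export
print.immune_params <- function(x, ...) {
  cat(sprintf(
    "<immune_params> popsize=%d maxgen=%d qc=%.2f qm=%.2f lambda=%.2f k=%.2f mc=%d stall=%d seed=%d\n",
    x$popsize, x$maxgen, x$qc, x$qm, x$lambda, x$k, x$mc, x$stall_gens, x$seed))
  invisible(x)
}
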