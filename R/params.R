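#' Parameters for the stochastic selection simulator
#'
#' Bundles the parameters of the rejection-kinetic branching-process model of
#' an exponentially growing tumour with stochastic driver arrival and
#' multiplicative fitness.
#'
#' @param mutation_rate Expected new mutations per genome per division
#'   (Poisson mean, each daughter cell draws independently). Must be >= 0.
#' @param p_driver Probability that any single new mutation is a driver, in
#'   `[0, 1]`. Driver arrival stops once `max_drivers` driver events occurred.
#' @param s_mean Mean of the exponential distribution from which selection
#'   coefficients `s > 0` are drawn. A driver multiplies the growth rate of
#'   its lineage by `(1 + s)`.
#' @param n_clonal Number of clonal mutations carried by the founder cell
#'   (true VAF exactly 0.5).
#' @param max_drivers Cap on the number of driver events (default 3).
#' @param n_final Final population size at virtual biopsy (default 1000).
#' @param birth_rate,death_rate Birth and death rates; require
#'   `birth_rate > death_rate >= 0`. Defaults `log(2)` and `0`.
#' @param max_retries Number of restarts allowed if the population goes
#'   extinct (only possible when `death_rate > 0`).
#' @param seed Optional integer RNG seed for [simulate_tumour()].
#'
#' @return A list of class `"selection_params"`.
#' @seealso [simulate_tumour()]
#' @export
selection_params <- function(mutation_rate = 100, p_driver = 1e-4,
                             s_mean = 1, n_clonal = 200, max_drivers = 3,
                             n_final = 1000, birth_rate = log(2),
                             death_rate = 0, max_retries = 100, seed = NULL) {
  p <- list(
    mutation_rate = mutation_rate, p_driver = p_driver, s_mean = s_mean,
    n_clonal = as.integer(n_clonal), max_drivers = as.integer(max_drivers),
    n_final = as.integer(n_final), birth_rate = birth_rate,
    death_rate = death_rate, max_retries = as.integer(max_retries),
    seed = seed
  )
  class(p) <- "selection_params"
  validate_selection_params(p)
  p
}

validate_selection_params <- function(p) {
  stop_unless(is.finite(p$mutation_rate) && p$mutation_rate >= 0,
              "`mutation_rate` must be finite and >= 0")
  stop_unless(is.finite(p$p_driver) && p$p_driver >= 0 && p$p_driver <= 1,
              "`p_driver` must be in [0, 1]")
  stop_unless(is.finite(p$s_mean) && p$s_mean > 0, "`s_mean` must be > 0")
  stop_unless(p$n_clonal >= 0, "`n_clonal` must be >= 0")
  stop_unless(p$max_drivers >= 0, "`max_drivers` must be >= 0")
  stop_unless(p$n_final >= 2, "`n_final` must be >= 2")
  stop_unless(is.finite(p$birth_rate) && is.finite(p$death_rate) &&
                p$birth_rate > p$death_rate && p$death_rate >= 0,
              "need birth_rate > death_rate >= 0")
  invisible(p)
}

#' Parameters for the generative neutral VAF sampler
#'
#' @param pareto_shape Pareto shape `alpha` (> 0) of the neutral tail.
#' @param pareto_scale Pareto scale `m`, in `(0, 0.5)`; the minimum tail VAF.
#' @param n_tail Number of neutral-tail mutations.
#' @param n_clonal Number of clonal mutations placed at `clonal_center`.
#' @param p_trim Probability (in `[0, 0.1]`) that the low-frequency tail is
#'   trimmed below `trim_f`.
#' @param trim_f Trim frequency, in `[0.10, 0.30]`. `NULL` draws uniformly
#'   from that interval when trimming fires.
#' @param clonal_center Centre of the clonal cluster, in `[0.45, 0.50]`.
#' @param seed Optional integer RNG seed for [generate_neutral()].
#'
#' @return A list of class `"neutral_params"`.
#' @seealso [generate_neutral()], [sample_pareto()]
#' @export
neutral_params <- function(pareto_shape = 1, pareto_scale = 0.02,
                           n_tail = 500, n_clonal = 200, p_trim = 0.05,
                           trim_f = NULL, clonal_center = 0.5, seed = NULL) {
  p <- list(
    pareto_shape = pareto_shape, pareto_scale = pareto_scale,
    n_tail = as.integer(n_tail), n_clonal = as.integer(n_clonal),
    p_trim = p_trim, trim_f = trim_f, clonal_center = clonal_center,
    seed = seed
  )
  class(p) <- "neutral_params"
  validate_neutral_params(p)
  p
}

validate_neutral_params <- function(p) {
  stop_unless(is.finite(p$pareto_shape) && p$pareto_shape > 0,
              "`pareto_shape` must be > 0")
  stop_unless(is.finite(p$pareto_scale) && p$pareto_scale > 0 &&
                p$pareto_scale < 0.5, "`pareto_scale` must be in (0, 0.5)")
  stop_unless(p$n_tail >= 0 && p$n_clonal >= 0,
              "mutation counts must be >= 0")
  stop_unless(p$p_trim >= 0 && p$p_trim <= 0.1, "`p_trim` must be in [0, 0.1]")
  if (!is.null(p$trim_f)) {
    stop_unless(p$trim_f >= 0.10 && p$trim_f <= 0.30,
                "`trim_f` must be in [0.10, 0.30]")
  }
  stop_unless(p$clonal_center >= 0.45 && p$clonal_center <= 0.50,
              "`clonal_center` must be in [0.45, 0.50]")
  invisible(p)
}

#' Sequencing-noise parameters for the virtual biopsy
#'
#' Observed depth is drawn per site as `D_obs ~ Binomial(N, D/N)` and the
#' alternate read count as `R_obs ~ BetaBinomial(D_obs, p, rho)` with success
#' probability `p = VAF_true * purity`. `rho = 0` degenerates to a binomial.
#'
#' @param mean_depth Mean sequencing depth `D` (> 0), e.g. 50-250.
#' @param rho Beta-binomial overdispersion (intraclass correlation), in
#'   `[0, 1)`; empirical WGS values are typically below 0.01.
#' @param min_alt_reads Minimum alternate reads to call a mutation
#'   (default 2); records below are dropped.
#' @param purity Tumour cell fraction of the biopsy, in `(0, 1]`.
#' @param depth_pool Binomial pool size `N` used for depth sampling; defaults
#'   to the simulated population size at biopsy.
#'
#' @return A list of class `"sequencing_params"`.
#' @seealso [virtual_biopsy()]
#' @export
sequencing_params <- function(mean_depth = 100, rho = 0, min_alt_reads = 2,
                              purity = 1, depth_pool = NULL) {
  p <- list(mean_depth = mean_depth, rho = rho,
            min_alt_reads = as.integer(min_alt_reads), purity = purity,
            depth_pool = depth_pool)
  class(p) <- "sequencing_params"
  validate_sequencing_params(p)
  p
}

validate_sequencing_params <- function(p) {
  stop_unless(is.finite(p$mean_depth) && p$mean_depth > 0,
              "`mean_depth` must be > 0")
  stop_unless(is.finite(p$rho) && p$rho >= 0 && p$rho < 1,
              "`rho` must be in [0, 1)")
  stop_unless(p$min_alt_reads >= 0, "`min_alt_reads` must be >= 0")
  stop_unless(is.finite(p$purity) && p$purity > 0 && p$purity <= 1,
              "`purity` must be in (0, 1]")
  if (!is.null(p$depth_pool)) {
    stop_unless(p$depth_pool >= p$mean_depth,
                "`depth_pool` must satisfy mean_depth / depth_pool <= 1")
  }
  invisible(p)
}

#' Parameters for the deterministic-subclone simulator
#'
#' Birth-death branching growth in which a single subclone is founded by a
#' randomly chosen cell when the population first reaches `2^subclone_time`
#' cells; the subclone's net growth rate `(b - d)` is multiplied by
#' `subclone_fitness`.
#'
#' @param mutation_rate Neutral mutations per genome per division.
#' @param subclone_fitness Relative growth-rate advantage `1 + s` (>= 1);
#'   1 makes the subclone selectively neutral.
#' @param subclone_time Emergence time in tumour doublings (log2 of the
#'   population size at initiation), >= 0. Values with
#'   `2^subclone_time >= n_final` produce no subclone.
#' @param n_clonal Clonal mutations in the founder cell (default 500).
#' @param birth,death Birth and death rates (defaults 1 and 0.2).
#' @param n_final Final population size (default 10^4).
#' @param max_retries Restarts allowed on whole-population extinction.
#' @param seed Optional integer RNG seed.
#'
#' @return A list of class `"deterministic_sim_params"`.
#' @seealso [simulate_deterministic()]
#' @export
deterministic_sim_params <- function(mutation_rate = 20, subclone_fitness = 2,
                                     subclone_time = 6, n_clonal = 500,
                                     birth = 1, death = 0.2, n_final = 1e4,
                                     max_retries = 100, seed = NULL) {
  p <- list(mutation_rate = mutation_rate,
            subclone_fitness = subclone_fitness,
            subclone_time = subclone_time, n_clonal = as.integer(n_clonal),
            birth = birth, death = death, n_final = as.integer(n_final),
            max_retries = as.integer(max_retries), seed = seed)
  class(p) <- "deterministic_sim_params"
  stop_unless(p$mutation_rate >= 0, "`mutation_rate` must be >= 0")
  stop_unless(p$subclone_fitness >= 1, "`subclone_fitness` must be >= 1")
  stop_unless(p$subclone_time >= 0, "`subclone_time` must be >= 0")
  stop_unless(p$death < p$birth, "need death < birth")
  stop_unless(p$death >= 0, "need death >= 0")
  stop_unless(p$n_final >= 2, "`n_final` must be >= 2")
  p
}

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg, class = "vafevo_validation_error")
  invisible(TRUE)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
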