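# Parameter sweeps over grids of configurations.

#' Derive per-run seeds from a master seed
#'
#' Reproducible sub-seeds for a sweep: seeding the generator once with the
#' master seed and drawing the required count of distinct integers, all
#' below 2^31.
#'
#' @param n_runs number of seeds needed.
#' @param master_seed integer master seed.
#' @return integer vector of `n_runs` distinct seeds.
#' @export
derive_seeds <- function(n_runs, master_seed) {
  stopifnot(n_runs >= 1)
  set.seed(master_seed)
  sample.int(2147483646L, n_runs)
}

#' Run a grid of configurations
#'
#' Each row of `grid` overrides the corresponding arguments of
#' [simulation_config()] (columns must be named after its arguments, e.g.
#' `N`, `b`, `c`, `lam`, `delta`, `R`, `T`, `rule`). Every configuration is
#' run with `seeds` replicate seeds derived reproducibly from
#' `master_seed`; the combined recorded metrics are returned with the grid
#' columns and a `config_id` prepended.
#'
#' @param grid data.frame of configuration overrides, one row per
#'   configuration; must be non-empty.
#' @param seeds number of replicate seeds per configuration.
#' @param master_seed integer master seed for [derive_seeds()].
#' @param ... further arguments passed to every [simulation_config()].
#' @param use_compiled passed to [run_simulation()].
#' @return data.frame of metrics rows with config columns prepended.
#' @examples
#' grid <- expand.grid(N = c(10, 20), b = 10 / 11)
#' grid$c <- 1 - grid$b
#' out <- run_sweep(grid, seeds = 2, master_seed = 1, T = 50,
#'                  record_every = 50)
#' @export
run_sweep <- function(grid, seeds = 1, master_seed = 1, ...,
                      use_compiled = TRUE) {
  if (!is.data.frame(grid) || nrow(grid) == 0)
    stop("grid must be a non-empty data.frame of configuration overrides")
  bad <- setdiff(names(grid), names(formals(simulation_config)))
  if (length(bad))
    stop("unknown configuration column(s): ", paste(bad, collapse = ", "))
  n_runs <- nrow(grid) * seeds
  seed_vec <- derive_seeds(n_runs, master_seed)
  key <- paste(rep(seq_len(nrow(grid)), each = seeds), seed_vec)
  if (anyDuplicated(key)) stop("duplicate (config, seed) pair in sweep")
  fixed <- list(...)
  out <- vector("list", n_runs)
  run <- 0L
  for (g in seq_len(nrow(grid))) {
    overrides <- as.list(grid[g, , drop = FALSE])
    overrides <- lapply(overrides, function(v) if (is.factor(v)) as.character(v) else v)
    for (r in seq_len(seeds)) {
      run <- run + 1L
      args <- c(overrides, fixed)
      args$seed <- seed_vec[run]
      cfg <- do.call(simulation_config, args)
      sim <- run_simulation(cfg, use_compiled = use_compiled)
      cfg_cols <- data.frame(config_id = g, overrides,
                             check.names = FALSE, stringsAsFactors = FALSE)
      out[[run]] <- cbind(cfg_cols[rep(1L, nrow(sim$metrics)), , drop = FALSE],
                          sim$metrics, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
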