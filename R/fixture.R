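#' Configuration for the synthetic mixture-of-cell-lines fixture
#'
#' Describes a benchmark dataset that emulates a designed cell-line mixture
#' experiment: a fixed number of cell lines, each carrying a disjoint
#' line-specific gene program, profiled under several protocols that differ
#' only in sequencing depth. Counts are Poisson:
#' `y_ij ~ Poisson(s_i * b_j * e_ij)` where `b_j` is a per-gene baseline
#' mean, `s_i` the protocol-specific library scale of cell `i`, and
#' `e_ij = 1 + (program_effect - 1) * a_i` when gene `j` belongs to the
#' program of cell `i`'s line (1 otherwise), with `a_i` a per-cell program
#' activity drawn log-normal with mean 1. The activity term reflects that
#' gene programs are not uniformly active across the cells of a line; it
#' also gives each line its own variance direction, without which the
#' between-line signal would be confined to a rank n_lines - 1 subspace
#' and no factorization could match every line to its own factor.
#' `program_activity_sd = 0` recovers the fixed-effect model.
#'
#' @param n_cells_per_group cells per (line, protocol) group (default 50).
#' @param n_genes total genes (default 300).
#' @param n_lines number of cell lines (default 3).
#' @param n_protocols number of protocols (default 3).
#' @param program_size genes in each line-specific program (default 20);
#'   programs are disjoint across lines.
#' @param program_effect multiplicative fold change of program genes in
#'   their line (default 3; must be > 1 for a non-degenerate signal, = 1 is
#'   allowed and produces a null dataset).
#' @param program_activity_sd log-scale standard deviation of the per-cell
#'   program activity `a_i` (default 0.5; 0 disables within-line activity
#'   variation).
#' @param libsize_spread protocol-specific library scale factors, length
#'   `n_protocols` (default `c(1, 2, 4)` truncated/recycled as needed).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean `b_j` (defaults `log(0.5)` and 1).
#' @param seed RNG seed; generation is a pure function of the config.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_cells_per_group = 50L, n_genes = 300L,
                           n_lines = 3L, n_protocols = 3L,
                           program_size = 20L, program_effect = 3,
                           program_activity_sd = 0.5,
                           libsize_spread = c(1, 2, 4),
                           baseline_meanlog = log(0.5), baseline_sdlog = 1,
                           seed = 1L) {
  cfg <- list(n_cells_per_group = as.integer(n_cells_per_group),
              n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
              n_protocols = as.integer(n_protocols),
              program_size = as.integer(program_size),
              program_effect = program_effect,
              program_activity_sd = program_activity_sd,
              libsize_spread = rep_len(libsize_spread, n_protocols),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              seed = as.integer(seed))
  if (cfg$n_cells_per_group < 1L || cfg$n_genes < 2L)
    stop("fixture needs at least 1 cell per group and 2 genes",
         call. = FALSE)
  if (cfg$program_effect < 1)
    stop("program_effect must be >= 1", call. = FALSE)
  if (cfg$n_lines * cfg$program_size > cfg$n_genes)
    stop("disjoint line programs require n_lines * program_size <= n_genes",
         call. = FALSE)
  if (any(cfg$libsize_spread <= 0))
    stop("libsize_spread must be positive", call. = FALSE)
  class(cfg) <- "fixture_config"
  cfg
}

#' Generate the synthetic benchmark dataset
#'
#' Draws counts from the model described in [fixture_config] and returns the
#' count matrix together with its covariate table (`line`, `protocol`,
#' `library_size`). The true program gene sets are attached for reference.
#'
#' @param config a [fixture_config] (default configuration if omitted).
#' @return A list with elements `counts` ([count_matrix]), `covariates`
#'   ([covariate_table]) and `programs` (list of program gene ids per line).
#' @export
make_fixture_dataset <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, {
    n_groups <- config$n_lines * config$n_protocols
    n <- n_groups * config$n_cells_per_group
    g <- config$n_genes
    line <- rep(rep(paste0("line", seq_len(config$n_lines)),
                    each = config$n_cells_per_group), config$n_protocols)
    protocol <- rep(paste0("protocol", seq_len(config$n_protocols)),
                    each = config$n_cells_per_group * config$n_lines)
    gene_ids <- sprintf("gene%03d", seq_len(g))
    programs <- split(gene_ids[seq_len(config$n_lines * config$program_size)],
                      rep(seq_len(config$n_lines), each = config$program_size))
    names(programs) <- paste0("line", seq_len(config$n_lines))

    b <- stats::rlnorm(g, config$baseline_meanlog, config$baseline_sdlog)
    s <- config$libsize_spread[match(protocol,
                                     paste0("protocol",
                                            seq_len(config$n_protocols)))]
    effect <- matrix(1, n, g)
    asd <- config$program_activity_sd
    activity <- if (asd > 0)
      stats::rlnorm(n, meanlog = -asd^2 / 2, sdlog = asd)
    else rep(1, n)
    for (ln in names(programs)) {
      idx <- match(programs[[ln]], gene_ids)
      sel <- line == ln
      effect[sel, idx] <- 1 + (config$program_effect - 1) * activity[sel]
    }
    mu <- (s %o% b) * effect
    counts <- matrix(stats::rpois(n * g, mu), n, g)
    cm <- count_matrix(counts,
                       cell_ids = sprintf("cell%04d", seq_len(n)),
                       gene_ids = gene_ids)
    cov <- covariate_table(
      data.frame(line = line, protocol = protocol,
                 library_size = unname(rowSums(cm$counts)),
                 stringsAsFactors = FALSE),
      cm$cell_ids)
    list(counts = cm, covariates = cov, programs = programs)
  })
}
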