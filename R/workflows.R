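# command-line workflows: thin orchestration over the analysis functions.
# Every workflow writes its resolved configuration to a YAML sidecar so any
# output file is reproducible from its sidecar alone.

wf_log <- function(quiet, ...) if (!isTRUE(quiet)) message(...)

write_sidecar <- function(config, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".config.yaml"))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Screen analysis workflow: rank genes and flag entries
#'
#' Reads a z-matrix TSV, runs the requested consensus ranking methods,
#' and writes to `out_dir`: a combined per-gene table
#' (`gene_table.tsv`), the entry-outlier table (`entry_outliers.tsv`, when
#' cellMCD is run), pairwise overlap counts at the significance threshold
#' (`overlap_counts.tsv`), and the top-k z-statistics of each method
#' (`topk_<method>.tsv`, annotated with the sign and a
#' `|z| > cutoff` intensity indicator for heatmap rendering).
#'
#' @param input Path to the z-matrix TSV (see [read_zmatrix()]).
#' @param out_dir Output directory (created if needed).
#' @param methods Methods to run, among `"fisher"`, `"ssz"`, `"cellmcd"`.
#' @param alpha Significance threshold on consensus p-values (default 0.01).
#' @param cutoff Entry-outlier residual cutoff (default 2.5758).
#' @param top_k Genes per top-k table (default 25, capped at the gene
#'   count).
#' @param standardize Standardize raw score columns first (see
#'   [read_zmatrix()]).
#' @param bh Append Benjamini-Hochberg q-values to the gene table.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the ranking results, overlap counts, the
#'   entry table and the paths written.
#' @export
run_rank_workflow <- function(input, out_dir, methods = c("fisher", "ssz", "cellmcd"),
                              alpha = 0.01, cutoff = sqrt(stats::qchisq(0.99, 1)),
                              top_k = 25, standardize = FALSE, bh = FALSE,
                              quiet = FALSE) {
  if (alpha <= 0 || alpha >= 1) zstop("alpha must be in (0, 1)")
  if (top_k < 1) zstop("top_k must be at least 1")
  methods <- match.arg(methods, several.ok = TRUE)
  z <- read_zmatrix(input, standardize = standardize)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- min(top_k, nrow(z))

  fit <- NULL
  results <- list()
  for (mth in methods) {
    results[[mth]] <- switch(mth,
      fisher = fisher_rank(z, bh = bh),
      ssz = ssz_rank(z, bh = bh),
      cellmcd = {
        fit <- fit_cellmcd(z)
        cellmcd_rank(z, fit = fit, bh = bh)
      })
    wf_log(quiet, sprintf("%s: %d of %d genes significant at p < %g",
                          mth, sum(results[[mth]]$pvalue < alpha), nrow(z),
                          alpha))
  }
  paths <- character(0)
  gt <- file.path(out_dir, "gene_table.tsv")
  write_gene_table(results, gt)
  paths <- c(paths, gt)

  entries <- NULL
  if (!is.null(fit)) {
    entries <- flag_entries(fit, cutoff = cutoff)
    ep <- file.path(out_dir, "entry_outliers.tsv")
    out <- entries
    for (j in c("z", "prediction", "cond_sd", "residual"))
      out[[j]] <- sprintf("%.12g", out[[j]])
    readr::write_tsv(out, ep, progress = FALSE)
    paths <- c(paths, ep)
    wf_log(quiet, sprintf(
      "cellMCD flagged %d entries with |residual| > %.4g (%d hidden: |z| < cutoff)",
      nrow(entries), cutoff, sum(entries$hidden)))
  }

  overlaps <- NULL
  if (length(methods) > 1L) {
    prs <- utils::combn(methods, 2, simplify = FALSE)
    overlaps <- purrr::map_dfr(prs, function(pr)
      overlap_counts(results[[pr[1]]], results[[pr[2]]], threshold = alpha))
    op <- file.path(out_dir, "overlap_counts.tsv")
    readr::write_tsv(overlaps, op, progress = FALSE)
    paths <- c(paths, op)
  }

  for (mth in methods) {
    tk <- topk_zmatrix(results[[mth]], z, k = k)
    long <- tidyr::pivot_longer(tk, -"gene", names_to = "phenotype",
                                values_to = "z") |>
      dplyr::mutate(sign = sign(.data$z),
                    strong = as.integer(abs(.data$z) > cutoff))
    tp <- file.path(out_dir, paste0("topk_", mth, ".tsv"))
    readr::write_tsv(long, tp, progress = FALSE)
    paths <- c(paths, tp)
  }
  write_sidecar(list(workflow = "rank", input = input, methods = methods,
                     alpha = alpha, cutoff = cutoff, top_k = k,
                     standardize = standardize, bh = bh),
                out_dir, "rank")
  invisible(list(results = results, overlaps = overlaps, entries = entries,
                 fit = fit, paths = paths))
}

#' Simulation workflow: write one simulated dataset
#'
#' Writes the simulated z-matrix (`dataset.tsv`), a label sidecar
#' (`labels.tsv` with per-row outlier labels and per-cell contamination
#' flags in long form), and the resolved configuration.
#'
#' @inheritParams simulate_dataset
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `sim_dataset` and the paths written.
#' @export
run_simulate_workflow <- function(out_dir, d = 5, n = 1000,
                                  correlation = "independent",
                                  mechanism = "rows", perout = 0.01,
                                  gamma = 0.25, seed = 1, quiet = FALSE) {
  sim <- simulate_dataset(d = d, n = n, correlation = correlation,
                          mechanism = mechanism, perout = perout,
                          gamma = gamma, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dp <- file.path(out_dir, "dataset.tsv")
  write_zmatrix(sim$values, dp)
  labels <- tibble::tibble(gene = sim$values$gene,
                           row_outlier = sim$row_labels,
                           replaced_row = sim$replaced_rows,
                           n_contaminated_cells = rowSums(sim$cell_labels))
  lp <- file.path(out_dir, "labels.tsv")
  readr::write_tsv(labels, lp, progress = FALSE)
  write_sidecar(list(workflow = "simulate", d = d, n = n,
                     correlation = correlation, mechanism = mechanism,
                     perout = perout, gamma = gamma, seed = seed),
                out_dir, "simulate")
  wf_log(quiet, sprintf("wrote %d x %d dataset with %d outlier rows", n, d,
                        sum(sim$row_labels)))
  invisible(list(sim = sim, paths = c(dp, lp)))
}

#' Evaluation workflow: AUC benchmark over a setting grid
#'
#' @param out_dir Output directory.
#' @param grid A settings tibble (see [simulation_grid()]), or the path to
#'   a YAML file holding a list of settings; `NULL` runs the full grid.
#' @param reps Replicates per setting.
#' @param methods Methods to compare.
#' @param seed Root seed.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary tibble and the path written.
#' @export
run_evaluate_workflow <- function(out_dir, grid = NULL, reps = 100,
                                  methods = c("fisher", "ssz", "cellmcd"),
                                  seed = 1, quiet = FALSE) {
  if (is.character(grid)) {
    grid <- purrr::map_dfr(yaml::read_yaml(grid), tibble::as_tibble)
  } else if (is.null(grid)) {
    grid <- simulation_grid()
  }
  summary <- run_grid(grid, r = reps, methods = methods, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(out_dir, "auc_summary.tsv")
  readr::write_tsv(summary, sp, progress = FALSE)
  write_sidecar(list(workflow = "evaluate", reps = reps, methods = methods,
                     seed = seed, settings = nrow(grid)),
                out_dir, "evaluate")
  wf_log(quiet, sprintf("evaluated %d settings x %d methods at r = %d",
                        nrow(grid), length(methods), reps))
  invisible(list(summary = summary, paths = sp))
}

#' Calibration workflow: the bivariate RMSD experiment
#'
#' @param out_dir Output directory.
#' @param n,rho,seed See [fit_rmsd_experiment()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the RMSD tibble and the path written.
#' @export
run_fig1_workflow <- function(out_dir, n = 10000, rho = 0.5, seed = 1,
                              quiet = FALSE) {
  res <- fit_rmsd_experiment(n = n, rho = rho, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(out_dir, "rmsd.tsv")
  readr::write_tsv(res, rp, progress = FALSE)
  write_sidecar(list(workflow = "fig1", n = n, rho = rho, seed = seed),
                out_dir, "fig1")
  wf_log(quiet, paste(sprintf("%s RMSD %.4g", res$method, res$rmsd),
                      collapse = "; "))
  invisible(list(rmsd = res, paths = rp))
}

#' Command-line dispatcher
#'
#' Parses `rank` / `simulate` / `evaluate` / `fig1` subcommands for the
#' installed `zscreen-cli.R` script and runs the matching workflow.
#' Exit status: 0 on success, 1 on a runtime failure, 2 on a usage or
#' validation error.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return The integer exit status, invisibly.
#' @export
zscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: zscreen-cli.R <rank|simulate|evaluate|fig1> [options]",
    "  rank:     --input FILE --out-dir DIR [--methods a,b] [--alpha P]",
    "            [--cutoff C] [--top-k K] [--standardize] [--quiet]",
    "  simulate: --out-dir DIR [--dim D] [--n N] [--correlation KIND]",
    "            [--mechanism M] [--perout P] [--gamma G] [--seed S]",
    "  evaluate: --out-dir DIR [--grid YAML] [--reps R] [--methods a,b]",
    "            [--seed S]",
    "  fig1:     --out-dir DIR [--n N] [--rho R] [--seed S]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  if (is.null(opts)) return(invisible(2L))
  status <- tryCatch({
    switch(cmd,
      rank = {
        if (is.null(opts$input)) zstop("--input is required",
                                       class = "zscreen_usage_error")
        run_rank_workflow(opts$input, opts$`out-dir` %||% ".",
                          methods = opts$methods %||% c("fisher", "ssz", "cellmcd"),
                          alpha = opts$alpha %||% 0.01,
                          cutoff = opts$cutoff %||% sqrt(stats::qchisq(0.99, 1)),
                          top_k = opts$`top-k` %||% 25,
                          standardize = isTRUE(opts$standardize),
                          quiet = isTRUE(opts$quiet))
      },
      simulate = run_simulate_workflow(
        opts$`out-dir` %||% ".", d = opts$dim %||% 5, n = opts$n %||% 1000,
        correlation = opts$correlation %||% "independent",
        mechanism = opts$mechanism %||% "rows",
        perout = opts$perout %||% 0.01, gamma = opts$gamma %||% 0.25,
        seed = opts$seed %||% 1, quiet = isTRUE(opts$quiet)),
      evaluate = run_evaluate_workflow(
        opts$`out-dir` %||% ".", grid = opts$grid,
        reps = opts$reps %||% 100,
        methods = opts$methods %||% c("fisher", "ssz", "cellmcd"),
        seed = opts$seed %||% 1, quiet = isTRUE(opts$quiet)),
      fig1 = run_fig1_workflow(
        opts$`out-dir` %||% ".", n = opts$n %||% 10000,
        rho = opts$rho %||% 0.5, seed = opts$seed %||% 1,
        quiet = isTRUE(opts$quiet)),
      { message("unknown subcommand: ", cmd, "\n", usage)
        return(invisible(2L)) })
    0L
  },
  zscreen_usage_error = function(e) { message(conditionMessage(e)); 2L },
  zscreen_io_error = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

# minimal --key value / --flag parser; numeric-looking values are converted,
# comma-separated values become vectors
parse_cli_options <- function(args) {
  flags <- c("standardize", "quiet", "debug")
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) { message("unexpected argument: ", a); return(NULL) }
    key <- substring(a, 3)
    if (key %in% flags) { opts[[key]] <- TRUE; i <- i + 1L; next }
    if (i + 1L > length(args)) { message("missing value for --", key); return(NULL) }
    val <- args[i + 1L]
    if (grepl(",", val, fixed = TRUE)) val <- strsplit(val, ",")[[1]]
    num <- suppressWarnings(as.numeric(val))
    if (all(!is.na(num))) val <- num
    opts[[key]] <- val
    i <- i + 2L
  }
  opts
}
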