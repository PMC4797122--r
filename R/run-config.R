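# resolve a flat key-value config against defaults, keeping every
# defaulted field explicit so run metadata is complete
.resolve_config <- function(config, defaults) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, config)
}

.similarity_defaults <- function() {
  list(compounds = NULL, kernel = "lingosim", q = 4L,
       weights = c(0.33, 0.33, 0.33), min_len = 2L, normalize = TRUE,
       alphabet = "smifp34", composite = NULL, lambda = 0.5,
       precision = 6L, out = "similarity.tsv")
}

#' Compute and write a compound similarity matrix from a config
#'
#' Reads a compound list, evaluates the configured kernel pairwise
#' (optionally mixing with a precomputed 2D matrix via
#' [composite_kernel()]), and writes the labeled TSV with the resolved
#' configuration embedded as header comments.
#'
#' @param config Named list; recognized keys and defaults: `compounds`
#'   (path, required), `kernel` ("lingosim"), `q` (4), `weights`
#'   (0.33 x3), `min_len` (2), `normalize` (TRUE), `alphabet`
#'   ("smifp34"), `composite` (optional path to a precomputed matrix),
#'   `lambda` (0.5), `precision` (6), `out` ("similarity.tsv").
#' @return The written `similarity_matrix`, invisibly.
#' @export
run_similarity <- function(config) {
  cfg <- .resolve_config(config, .similarity_defaults())
  if (is.null(cfg$compounds)) abort("config needs `compounds` (path)")
  t0 <- Sys.time()
  corpus <- read_compound_list(cfg$compounds)
  S <- pairwise_similarity(corpus, method = cfg$kernel, q = cfg$q,
                           weights = cfg$weights, min_len = cfg$min_len,
                           normalize = cfg$normalize, alphabet = cfg$alphabet)
  if (!is.null(cfg$composite)) {
    S2d <- read_similarity_matrix(cfg$composite)
    S <- composite_kernel(S2d, S, lambda = cfg$lambda)
  }
  write_similarity_matrix(S, cfg$out, precision = cfg$precision)
  message(sprintf("kernel=%s compounds=%d wall=%.2fs -> %s", cfg$kernel,
                  nrow(corpus), as.numeric(Sys.time() - t0, units = "secs"),
                  cfg$out))
  invisible(S)
}

.evaluate_defaults <- function() {
  c(.similarity_defaults()[c("compounds", "q", "weights", "min_len",
                             "normalize", "alphabet", "composite", "lambda")],
    list(kernel = "lingosim", adjacency = NULL, target_sim = NULL,
         n_folds = 5L, n_repeats = 5L, seed = 1L,
         gamma_scale = 1, alpha = 0.5, sigma = 1, wnn_decay = 0.7,
         wnn_enabled = TRUE, out = "evaluation.tsv"))
}

#' Run repeated cross-validation from a config
#'
#' Loads the compound list, adjacency and target similarity files, builds
#' the configured drug kernel(s), runs [cross_validate()] for each, and
#' writes a summary report (one row per kernel: mean and sd of AUC-ROC and
#' AUC-PR over folds and over repeat means, plus wall time). `kernel` may
#' be a vector; all kernels share the same seed so [paired_ttest()] applies
#' to the per-fold results.
#'
#' @param config Named list; keys of [run_similarity()] plus `adjacency`
#'   and `target_sim` (paths, required), `n_folds` (5), `n_repeats` (5),
#'   `seed` (1), `gamma_scale` (1), `alpha` (0.5), `sigma` (1),
#'   `wnn_decay` (0.7), `wnn_enabled` (TRUE), `out` ("evaluation.tsv").
#' @return List with `report` (tibble) and `results` (named list of
#'   `cv_result`), invisibly.
#' @export
run_evaluate <- function(config) {
  cfg <- .resolve_config(config, .evaluate_defaults())
  for (key in c("compounds", "adjacency", "target_sim")) {
    if (is.null(cfg[[key]])) abort(sprintf("config needs `%s` (path)", key))
  }
  corpus <- read_compound_list(cfg$compounds)
  network <- read_interaction_network(cfg$adjacency)
  target_sim <- read_similarity_matrix(cfg$target_sim)
  missing_drugs <- setdiff(network$drug_ids, corpus$id)
  if (length(missing_drugs)) {
    abort(paste0("network drugs absent from the compound list: ",
                 paste(head(missing_drugs, 5L), collapse = ", ")))
  }
  if (!setequal(network$target_ids, rownames(target_sim))) {
    abort("target ids differ between adjacency and target similarity files")
  }
  corpus <- corpus[match(network$drug_ids, corpus$id), ]
  target_sim <- similarity_matrix(
    unclass(target_sim)[network$target_ids, network$target_ids],
    network$target_ids, method = attr(target_sim, "method"))
  gconf <- gip_config(cfg$gamma_scale, cfg$alpha, cfg$sigma, cfg$wnn_decay,
                      cfg$wnn_enabled)
  S2d <- if (!is.null(cfg$composite)) {
    M <- read_similarity_matrix(cfg$composite)
    similarity_matrix(unclass(M)[network$drug_ids, network$drug_ids],
                      network$drug_ids, method = "precomputed")
  }
  results <- list()
  report <- list()
  for (kern in cfg$kernel) {
    t0 <- Sys.time()
    S <- pairwise_similarity(corpus, method = kern, q = cfg$q,
                             weights = cfg$weights, min_len = cfg$min_len,
                             normalize = cfg$normalize,
                             alphabet = cfg$alphabet)
    label <- kern
    if (!is.null(S2d)) {
      S <- composite_kernel(S2d, S, lambda = cfg$lambda)
      label <- paste0(kern, "+2D")
    }
    cv <- cross_validate(network, S, target_sim, config = gconf,
                         n_folds = cfg$n_folds, n_repeats = cfg$n_repeats,
                         seed = cfg$seed, method = label)
    g <- glance(cv)
    g$wall_sec <- as.numeric(Sys.time() - t0, units = "secs")
    results[[label]] <- cv
    report[[label]] <- g
  }
  report <- dplyr::bind_rows(report)
  con <- file(cfg$out, "w")
  meta <- cfg[!vapply(cfg, is.null, TRUE)]
  writeLines(sprintf("# %s", paste(names(meta),
                                   vapply(meta, function(v) paste(format(v), collapse = ","), ""),
                                   sep = "=", collapse = " ")), con)
  close(con)
  suppressWarnings(utils::write.table(report, cfg$out, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  message(sprintf("evaluated %d kernel(s) -> %s", length(cfg$kernel), cfg$out))
  invisible(list(report = report, results = results))
}
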