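#' Default run configuration
#'
#' All tunable parameters of the two scoring workflows with their defaults:
#' the high-expression filter threshold (`filter_z`), the random-profile
#' null size and threshold multiplier (`null_reps`, `multiplier`), the
#' gene-set stage parameters (`pool`, `size`, `tau`, `prior`, `min_total`)
#' and the RNG `seed`. Unknown keys are rejected so typos fail loudly.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of configuration values.
#' @export
lap_config <- function(...) {
  defaults <- list(
    filter_z = 1.0, null_reps = 10000L, multiplier = 5,
    pool = 3000L, size = 100L, tau = 1, prior = 0.5, min_total = 2,
    seed = 0L,
    # simulate-stage parameters
    genes = 2000L, types = 8L, rho = 0.5, noise_sd = 0.2,
    dispersion = 0.2, cells_per_cluster = 50L, dropout = 0.2
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, overrides)
}

#' Run one pipeline stage and write its artifacts
#'
#' The command-line surface of the package: each command reads its inputs,
#' runs the corresponding package functions, and writes self-describing
#' outputs (every stage directory carries a `meta.json` recording the full
#' configuration, seed and package version, so a run can be reproduced
#' bit-for-bit).
#'
#' * `simulate` — write a synthetic cross-platform reference (TSV per
#'   platform), a single-cell count matrix (MTX + sidecars) and
#'   `truth.json`.
#' * `build-basis` — assemble a basis from expression TSVs (`inputs`) and
#'   serialize it.
#' * `calibrate` — random-profile null for a serialized basis
#'   (`basis_dir`), written to `calibration.json`.
#' * `project` — normalize query TSVs (`inputs`) onto a basis, score and
#'   flag them against `calibration.json`, write `scores.tsv`.
#' * `gsa` — preprocess a count TSV (`inputs`), build per-condition
#'   signatures (`conditions`, one label per sample), write them as GMT and
#'   the enrichment-score table as TSV.
#'
#' @param command One of `"simulate"`, `"build-basis"`, `"calibrate"`,
#'   `"project"`, `"gsa"`.
#' @param out Output directory.
#' @param inputs Character vector of input paths (stage-dependent).
#' @param basis_dir Directory of a serialized basis (project / calibrate).
#' @param conditions Condition label per sample column (gsa).
#' @param config A list from [lap_config()].
#' @return Invisibly, the output directory.
#' @export
lap_run <- function(command = c("simulate", "build-basis", "calibrate",
                                "project", "gsa"),
                    out, inputs = character(), basis_dir = NULL,
                    conditions = NULL, config = lap_config()) {
  command <- match.arg(command)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- lap_config(config)

  res <- tryCatch(switch(command,
    "simulate" = {
      ref <- simulate_reference(G = cfg$genes, K = cfg$types, rho = cfg$rho,
                                seed = cfg$seed, dispersion = cfg$dispersion)
      purrr::iwalk(ref$matrices, function(m, nm) {
        write_expression(m, file.path(out, paste0("reference_", nm, ".tsv")))
      })
      sc <- simulate_single_cell(G = cfg$genes, n_clusters = 4L,
                                 cells_per_cluster = cfg$cells_per_cluster,
                                 dispersion = cfg$dispersion,
                                 dropout = cfg$dropout, seed = cfg$seed)
      write_expression(sc$counts, file.path(out, "single_cell.mtx"))
      readr::write_tsv(sc$clusters, file.path(out, "clusters.tsv"),
                       progress = FALSE)
      jsonlite::write_json(
        list(latent_correlation = stats::cor(ref$latent),
             types = ref$truth$type, platforms = ref$truth$platform,
             sc_clusters = sort(unique(sc$clusters$cluster))),
        file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
      message(sprintf("simulate: G=%d, K=%d, rho=%.2f", cfg$genes, cfg$types,
                      cfg$rho))
    },
    "build-basis" = {
      stopifnot(length(inputs) >= 1L)
      mats <- rlang::set_names(
        purrr::map(inputs, read_expression),
        tools::file_path_sans_ext(basename(inputs)))
      basis <- build_reference(mats, filter_z = cfg$filter_z)
      write_basis(basis, out)
      message(sprintf(
        "build-basis: K=%d types, %d genes survive z>%g filter (N=%d)",
        length(basis$type_labels), length(basis$gene_ids), cfg$filter_z,
        basis$n))
    },
    "calibrate" = {
      basis <- read_basis(require_artifact(basis_dir, "basis directory"))
      cal <- calibrate_null(basis, R = cfg$null_reps, seed = cfg$seed,
                            multiplier = cfg$multiplier)
      write_calibration(cal, file.path(out, "calibration.json"))
      message(sprintf("calibrate: R=%d, sd=%.4f, threshold=%.4f", cal$R,
                      cal$sd, cal$threshold))
    },
    "project" = {
      basis <- read_basis(require_artifact(basis_dir, "basis directory"))
      stopifnot(length(inputs) >= 1L)
      cal_path <- file.path(require_artifact(basis_dir, "basis directory"),
                            "calibration.json")
      scores <- purrr::map(inputs, function(p) {
        project_onto_basis(basis, normalize_query(basis, read_expression(p)))
      }) |> purrr::list_rbind()
      if (file.exists(cal_path)) {
        scores <- classify_significant(scores, read_calibration(cal_path))
      }
      write_scores(scores, file.path(out, "scores.tsv"))
      message(sprintf("project: %d sample(s) x %d types",
                      dplyr::n_distinct(scores$sample_id),
                      length(basis$type_labels)))
    },
    "gsa" = {
      stopifnot(length(inputs) == 1L, !is.null(conditions))
      counts <- read_expression(inputs, platform = "count")
      processed <- preprocess_counts(counts, min_total = cfg$min_total,
                                     prior = cfg$prior)
      pool <- min(cfg$pool, nrow(processed))
      sigs <- build_signatures(processed, conditions,
                               pool = pool, size = min(cfg$size, pool))
      write_gmt(sigs, file.path(out, "signatures.gmt"))
      es <- score_signatures(processed, sigs, tau = cfg$tau)
      readr::write_tsv(
        tidyr::pivot_wider(es, names_from = "sample_id",
                           values_from = "es"),
        file.path(out, "enrichment_scores.tsv"), progress = FALSE)
      message(sprintf("gsa: %d signatures x %d samples", length(sigs),
                      dplyr::n_distinct(es$sample_id)))
    }
  ), error = function(e) {
    stop(sprintf("[%s] %s", command, conditionMessage(e)), call. = FALSE)
  })

  # merge into any metadata already in the directory (e.g. write_basis's)
  meta_path <- file.path(out, "meta.json")
  existing <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  meta <- utils::modifyList(existing, c(
    list(command = command, inputs = inputs,
         basis_dir = basis_dir %||% NA, conditions = conditions %||% NA,
         version = as.character(utils::packageVersion("lapscore"))),
    cfg))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(out)
}

require_artifact <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("missing %s: %s", what, path %||% "<not given>"),
         call. = FALSE)
  }
  path
}
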