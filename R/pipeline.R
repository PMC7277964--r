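# Orchestration: load -> segment -> densitometry at the three thresholds
# -> GAP -> statistical reports, with a validated config and deterministic
# outputs.

#' Pipeline configuration
#'
#' @param volumes named character vector of NIfTI volume paths (names are
#'   patient ids), or `NULL` in simulation mode.
#' @param masks optional named character vector of NIfTI 0/1 mask paths;
#'   a patient with a supplied mask bypasses automatic segmentation.
#' @param clinical path to the clinical CSV (`patient_id, sex, age_years,
#'   fvc_pct_pred, dlco_pct_pred`) or a data.frame; optional if only
#'   densitometry is wanted.
#' @param thresholds upper HU thresholds to compute (subset of -200, 0,
#'   +200).
#' @param gap_response `"points"` (default) or `"stage"`: the response used
#'   by the Poisson model comparison.
#' @param output_dir directory for the written artifacts.
#' @param simulate if `TRUE`, ignore `volumes`/`clinical` and run on a
#'   synthetic cohort drawn from `cohort` (a [cohort_spec()]).
#' @param cohort a [cohort_spec()] used when `simulate = TRUE`.
#' @param seed RNG seed for the simulation mode.
#' @return a `run_config` list.
#' @export
run_config <- function(volumes = NULL, masks = NULL, clinical = NULL,
                       thresholds = LUNG_THRESHOLDS,
                       gap_response = c("points", "stage"),
                       output_dir = tempfile("lungdens_run_"),
                       simulate = FALSE, cohort = NULL, seed = 1L) {
  gap_response <- match.arg(gap_response)
  thresholds <- as.integer(thresholds)
  if (!all(thresholds %in% LUNG_THRESHOLDS))
    stopf("thresholds must be a subset of {-200, 0, 200}")
  structure(list(volumes = volumes, masks = masks, clinical = clinical,
                 thresholds = thresholds, gap_response = gap_response,
                 output_dir = output_dir, simulate = isTRUE(simulate),
                 cohort = cohort, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate pipeline inputs
#'
#' Reports (without failing) missing files, clinical-table schema
#' violations and mask/volume geometry mismatches.
#'
#' @param cfg a [run_config].
#' @return data.frame with columns `severity`, `item`, `message`; zero rows
#'   when everything is consistent.
#' @export
validate_inputs <- function(cfg) {
  probs <- list()
  add <- function(sev, item, msg)
    probs[[length(probs) + 1L]] <<- data.frame(severity = sev, item = item,
                                               message = msg)
  if (!cfg$simulate) {
    for (pid in names(cfg$volumes))
      if (!file.exists(cfg$volumes[[pid]]))
        add("error", pid, sprintf("volume file missing: %s", cfg$volumes[[pid]]))
    for (pid in names(cfg$masks)) {
      if (!file.exists(cfg$masks[[pid]])) {
        add("error", pid, sprintf("mask file missing: %s", cfg$masks[[pid]]))
      } else if (!is.null(cfg$volumes[[pid]]) &&
                   file.exists(cfg$volumes[[pid]])) {
        vol <- load_volume(cfg$volumes[[pid]])
        mk <- try(load_mask(cfg$masks[[pid]]), silent = TRUE)
        if (inherits(mk, "try-error")) {
          add("error", pid, "mask is not a 0/1 NIfTI")
        } else if (!identical(dim(mk$flags), dim(vol$voxels))) {
          add("error", pid,
              sprintf("mask grid (%s) does not match volume grid (%s)",
                      paste(dim(mk$flags), collapse = "x"),
                      paste(dim(vol$voxels), collapse = "x")))
        }
      }
    }
    if (is.character(cfg$clinical)) {
      if (!file.exists(cfg$clinical)) {
        add("error", "clinical", sprintf("clinical table missing: %s",
                                         cfg$clinical))
      } else {
        hdr <- names(utils::read.csv(cfg$clinical, nrows = 1))
        need <- c("patient_id", "sex", "age_years", "fvc_pct_pred",
                  "dlco_pct_pred")
        for (col in setdiff(need, hdr))
          add("error", "clinical", sprintf("missing column: %s", col))
      }
    }
  }
  if (length(probs)) do.call(rbind, probs)
  else data.frame(severity = character(), item = character(),
                  message = character())
}

pipeline_note <- function(msg) message("[lungdens] ", msg)

#' Run the full quantitative pipeline
#'
#' For every patient: load the volume, segment the lungs (automatic region
#' growing with trachea removal, unless a mask is supplied), build the
#' attenuation histogram, and compute the feature set at each configured
#' threshold. If a clinical table with at least five patients is present,
#' also computes GAP, the per-threshold correlation matrices, the Poisson
#' model comparison (ranked by log-likelihood) and the gamma models of FVC
#' and DLco on NL\%. All artifacts are written as CSV/JSON under
#' `cfg$output_dir`; outputs are a pure function of (inputs, config, seed).
#'
#' @param cfg a [run_config].
#' @return invisibly, a list with the in-memory results (`features` long
#'   table, `clinical`, `correlations`, `poisson`, `gamma`, `ranking`,
#'   `manifest`). On any stage failure a `FAILED` marker file is written
#'   and the error is re-thrown.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) writeLines("pipeline failed; partial outputs retained",
                              file.path(cfg$output_dir, "FAILED")))
  rep <- validate_inputs(cfg)
  if (any(rep$severity == "error")) {
    print(rep)
    stopf("invalid inputs: %d error(s); see the validation report",
          sum(rep$severity == "error"))
  }

  pipeline_note("PFF% is reported as the complement of the non-fibrotic fraction")
  pipeline_note("kurtosis is excess kurtosis (zero for a normal distribution)")
  pipeline_note(sprintf("Poisson response: GAP %s", cfg$gap_response))

  if (cfg$simulate) {
    cohort <- cfg$cohort %||% cohort_spec(seed = cfg$seed)
    sim <- generate_cohort(cohort)
    clinical <- sim$clinical
    features <- sim$features[sim$features$threshold_hu %in% cfg$thresholds, ]
  } else {
    clinical <- if (is.character(cfg$clinical)) read_clinical(cfg$clinical)
                else cfg$clinical
    fsets <- list()
    for (pid in names(cfg$volumes)) {
      vol <- load_volume(cfg$volumes[[pid]])
      mask <- if (!is.null(cfg$masks[[pid]]))
        load_mask(cfg$masks[[pid]], vol) else segment_lungs(vol)
      hist <- build_histogram(vol, mask)
      fsets[[pid]] <- compute_all_thresholds(hist, cfg$thresholds)
    }
    long <- features_to_table(fsets)
    features <- stats::reshape(long, idvar = c("patient_id", "threshold_hu"),
                               timevar = "feature", direction = "wide")
    names(features) <- sub("^value\\.", "", names(features))
    if (!is.null(clinical))
      features <- merge(features, clinical, by = "patient_id", sort = TRUE)
  }
  features <- features[order(features$patient_id, features$threshold_hu), ]
  rownames(features) <- NULL
  utils::write.csv(features, file.path(cfg$output_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(features, file.path(cfg$output_dir, "features.json"),
                       dataframe = "rows", digits = NA)

  correlations <- poisson <- gamma <- ranking <- NULL
  n_pat <- length(unique(features$patient_id))
  has_clin <- !is.null(clinical) && all(c("gap_points") %in% names(features))
  if (has_clin && n_pat >= 5L) {
    utils::write.csv(clinical, file.path(cfg$output_dir, "clinical_gap.csv"),
                     row.names = FALSE)
    correlations <- lapply(cfg$thresholds, function(th) {
      cm <- correlation_matrix(features, th)
      utils::write.csv(as.data.frame(cm$rho),
                       file.path(cfg$output_dir,
                                 sprintf("correlation_%d.csv", th)))
      cm
    })
    names(correlations) <- as.character(cfg$thresholds)
    resp <- if (cfg$gap_response == "points") "gap_points" else "gap_stage"
    poisson <- poisson_report(features, thresholds = cfg$thresholds,
                              response = resp)
    utils::write.csv(poisson$wide,
                     file.path(cfg$output_dir, "poisson_report.csv"),
                     row.names = FALSE)
    ranking <- rank_by_loglik(unlist(poisson$fits, recursive = FALSE,
                                     use.names = FALSE))
    utils::write.csv(ranking$table, file.path(cfg$output_dir, "ranking.csv"),
                     row.names = FALSE)
    gth <- intersect(c(-200L, 200L), cfg$thresholds)
    if (length(gth)) {
      gamma <- gamma_report(features, thresholds = gth)
      utils::write.csv(gamma, file.path(cfg$output_dir, "gamma_report.csv"),
                       row.names = FALSE)
    }
  }

  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "cohort")],
                               auto_unbox = TRUE, null = "null", force = TRUE)
  cfg_file <- file.path(cfg$output_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(package = "lungdens",
                   version = as.character(utils::packageVersion("lungdens")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   n_patients = n_pat,
                   thresholds = cfg$thresholds)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(list(features = features, clinical = clinical,
                 correlations = correlations, poisson = poisson,
                 gamma = gamma, ranking = ranking, manifest = manifest))
}
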