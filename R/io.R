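#' Read thermograms from long-format CSV
#'
#' One row per measurement with columns `patient_id`, `visit_date`, `side`
#' (`L`, `R`, `REF`), `point` (`0`-`9` for breast rows, `T1`/`T2` for
#' reference rows), `channel` (`mw` internal, `ir` skin) and `temp_c`
#' (degrees Celsius, `.` decimal separator). Row order is irrelevant;
#' unknown extra columns are ignored with a warning. Each
#' (patient, visit) must carry its full complement of 44 measurements;
#' missing or duplicated cells are reported with the offending
#' coordinates.
#'
#' @param path CSV file path.
#' @return A list of validated [thermogram] objects (one per
#'   patient/visit, in file order of first appearance).
#' @export
read_thermogram_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("patient_id", "visit_date", "side", "point", "channel",
                "temp_c")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  df$temp_c <- suppressWarnings(as.numeric(df$temp_c))
  bad <- which(is.na(df$temp_c))
  if (length(bad)) {
    stop("non-numeric temp_c at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df$side <- toupper(df$side)
  df$channel <- tolower(df$channel)
  if (!all(df$side %in% c("L", "R", "REF"))) {
    stop("side must be one of L, R, REF", call. = FALSE)
  }
  if (!all(df$channel %in% c("mw", "ir"))) {
    stop("channel must be 'mw' or 'ir'", call. = FALSE)
  }

  key <- paste(df$patient_id, df$visit_date, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    dup <- duplicated(sub[, c("side", "point", "channel")])
    if (any(dup)) {
      d <- sub[dup, ][1L, ]
      stop(sprintf("duplicate measurement for patient %s: side=%s point=%s channel=%s",
                   d$patient_id, d$side, d$point, d$channel), call. = FALSE)
    }
    cell <- function(side, point, channel) {
      i <- which(sub$side == side & sub$point == as.character(point) &
                   sub$channel == channel)
      if (length(i) != 1L) {
        stop(sprintf("patient %s, visit %s: missing measurement side=%s point=%s channel=%s",
                     sub$patient_id[1L], sub$visit_date[1L], side, point,
                     channel), call. = FALSE)
      }
      sub$temp_c[i]
    }
    tg <- thermogram(
      patient_id = sub$patient_id[1L],
      visit_date = sub$visit_date[1L],
      t_skin_right = vapply(POINT_IDS, cell, numeric(1), side = "R",
                            channel = "ir"),
      t_skin_left = vapply(POINT_IDS, cell, numeric(1), side = "L",
                           channel = "ir"),
      t_int_right = vapply(POINT_IDS, cell, numeric(1), side = "R",
                           channel = "mw"),
      t_int_left = vapply(POINT_IDS, cell, numeric(1), side = "L",
                          channel = "mw"),
      t_skin_ref = vapply(REF_IDS, cell, numeric(1), side = "REF",
                          channel = "ir"),
      t_int_ref = vapply(REF_IDS, cell, numeric(1), side = "REF",
                         channel = "mw")
    )
    .assert_valid_thermogram(tg)
    out[[length(out) + 1L]] <- tg
  }
  out
}

#' Write thermograms to the long-format CSV dialect
#'
#' @param tgs A [thermogram] or list of thermograms.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thermogram_csv <- function(tgs, path) {
  if (inherits(tgs, "thermogram")) tgs <- list(tgs)
  rows <- lapply(tgs, function(tg) {
    data.frame(
      patient_id = tg$patient_id,
      visit_date = format(tg$visit_date),
      side = c(rep(c("R", "L"), each = 10L), rep("REF", 2L),
               rep(c("R", "L"), each = 10L), rep("REF", 2L)),
      point = rep(c(as.character(POINT_IDS), as.character(POINT_IDS),
                    REF_IDS), 2L),
      channel = rep(c("ir", "mw"), each = 22L),
      temp_c = c(tg$t_skin_right, tg$t_skin_left, tg$t_skin_ref,
                 tg$t_int_right, tg$t_int_left, tg$t_int_ref),
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read an eight-marker panel CSV
#'
#' One row per marker with a `marker` column plus `norm_conc`/`path_conc`
#' (copies/uL) and/or a `label` column of expression categories.
#'
#' @param path CSV file path.
#' @return A data.frame ready for [panel_risk()].
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"marker" %in% names(df)) {
    stop("panel CSV needs a 'marker' column", call. = FALSE)
  }
  df
}

RESULTS_SCHEMA_VERSION <- "1.0"

.canonical_json <- function(x) {
  # fixed key order + unboxed scalars => byte-identical output
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                   null = "null")
}

#' Write a result object to versioned JSON
#'
#' Serializes an [score_mwr()] score, [panel_risk()] result or [assess()]
#' assessment to a stable, versioned JSON schema with sorted sections so
#' identical inputs produce byte-identical files.
#'
#' @param x An `mwr_score`, `panel_result` or `assessment` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  payload <- if (inherits(x, "mwr_score")) {
    list(schema_version = RESULTS_SCHEMA_VERSION, kind = "mwr_score",
         patient_id = x$patient_id, visit_date = format(x$visit_date),
         q_max = x$q_max, t_max_mw = x$t_max_mw, t_max_ir = x$t_max_ir,
         t_mean_mw = x$t_mean_mw, t_mean_ir = x$t_mean_ir,
         k_int = x$k_int, n_int = x$n_int,
         k_skin = x$k_skin, n_skin = x$n_skin,
         r = x$r, branch = x$branch,
         q_threshold = x$q_threshold, r_threshold = x$r_threshold,
         sign_convention = x$sign_convention, mwr_class = x$mwr_class)
  } else if (inherits(x, "panel_result")) {
    list(schema_version = RESULTS_SCHEMA_VERSION, kind = "panel_result",
         scores = as.list(x$scores),
         fold_reported = as.list(x$fold_reported),
         risk_sum = x$risk_sum, category = x$category,
         low_high_cutoff = x$low_high_cutoff)
  } else if (inherits(x, "assessment")) {
    list(schema_version = RESULTS_SCHEMA_VERSION, kind = "assessment",
         mwr_class = x$mwr_class,
         classifier_label = x$classifier_label,
         mirna_category = x$mirna_category,
         overall = x$overall, rationale = as.list(x$rationale))
  } else {
    stop("write_results: unsupported object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  writeLines(.canonical_json(payload), path)
  invisible(path)
}

#' Read back a JSON result written by [write_results()]
#' @param path JSON file path.
#' @return A named list with a `schema_version` and `kind` field.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Serialize a trained risk model to JSON
#' @param model A `risk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  payload <- list(
    schema_version = RESULTS_SCHEMA_VERSION, kind = "risk_model",
    model_kind = model$model_kind, features = as.list(model$features),
    center = as.list(model$center), scale = as.list(model$scale),
    parameters = model$parameters, training_meta = model$training_meta
  )
  writeLines(.canonical_json(payload), path)
  invisible(path)
}

#' Read a risk model serialized by [write_risk_model()]
#' @param path JSON file path.
#' @return A `risk_model` usable with [predict_risk()].
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$kind) || obj$kind != "risk_model") {
    stop("not a risk_model JSON file: ", path, call. = FALSE)
  }
  params <- obj$parameters
  if (obj$model_kind == "small_mlp") {
    params$n_in <- as.integer(params$n_in)
    params$n_hidden <- as.integer(params$n_hidden)
  }
  structure(
    list(model_kind = obj$model_kind, features = unlist(obj$features),
         center = unlist(obj$center), scale = unlist(obj$scale),
         parameters = params, training_meta = obj$training_meta),
    class = "risk_model"
  )
}

#' Default run configuration
#'
#' All tunable constants in one place: the MWR decision thresholds, the
#' fold-change risk bands and low/high cutoff of the oncopanel, the
#' asymmetry sign convention, the feature-space aggregate list, and the
#' generator parameters. Round-trips losslessly through YAML.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(
    list(
      q_threshold = 2.0,
      r_threshold = 2.5,
      mirna_bands = c(1.5, 2, 5),
      mirna_low_high_cutoff = 5,
      sign_convention = "absolute",
      feature_aggregates = .AGGREGATES,
      include_reference = FALSE,
      generator = list(skin_base = 31.5, int_base = 34.5, noise_sd = 0.25,
                       focus_delta_int = 3.0,
                       focus_gradient_reduction = 1.0,
                       panel_lognormal_sd = 0.25),
      seed = 1L
    ),
    class = "run_config"
  )
}

#' Write / read a run configuration as YAML
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `path` invisibly (write); a `run_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  structure(yaml::read_yaml(path), class = "run_config")
}
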