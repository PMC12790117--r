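# Validated readers and writers for the patient, site and survey tables.
#
# Interchange is delimited text (CSV, UTF-8, comma, quoted strings), one row
# per patient with day-indexed wide columns (d1_..d7_) mirroring the 7-day
# daily assessment of the case report form. Missing values are empty fields,
# never sentinel numbers. Validation is total: every row is either accepted
# as a well-typed record or produces a located error; no silent coercion
# (the one documented shim: FiO2 entered as a percentage > 1 is divided by
# 100 and the coercion logged as a note).

#' Data dictionary for the patient table
#'
#' One row per column of the patient CSV: name, type, units, allowed levels,
#' whether the column is mandatory, and numeric bounds. Day-indexed columns
#' (\code{d1_spo2_min} .. \code{d7_map_cmh2o}) cover the first seven hospital
#' days (day 1 = admission day). A copy is shipped as
#' \code{extdata/patients_dictionary.csv}.
#'
#' @return data frame with columns \code{column}, \code{type}
#'   (\code{id|character|numeric|logical|enum}), \code{units},
#'   \code{allowed} (pipe-separated enum levels), \code{required},
#'   \code{min}, \code{max}.
#' @export
patient_dictionary <- function() {
  row <- function(column, type, units = "", allowed = "", required = TRUE,
                  min = NA, max = NA) {
    data.frame(column = column, type = type, units = units, allowed = allowed,
               required = required, min = min, max = max,
               stringsAsFactors = FALSE)
  }
  fixed <- rbind(
    row("patient_id", "id"),
    row("site_id", "id"),
    row("age_years", "numeric", "years", min = 29 / 365, max = 14),
    row("sex", "enum", allowed = "F|M"),
    row("weight_kg", "numeric", "kg", min = 0.5, max = 150),
    row("admission_spo2_pct", "numeric", "%", min = 0, max = 100),
    row("muac_cm", "numeric", "cm", min = 3, max = 40),
    row("waz", "numeric", "z-score", min = -10, max = 10),
    row("reported_malnutrition", "logical"),
    row("cyanotic_chd", "logical"),
    row("prior_pulmonary_disease", "logical"),
    row("lods_prostration_or_feed", "logical"),
    row("lods_coma", "logical"),
    row("lods_deep_breathing", "logical"),
    row("final_diagnoses", "character"),
    row("cxr_obtained", "logical"),
    row("cxr_opacity", "logical"),
    row("cxr_opacity_attributed_nonparenchymal", "logical"),
    row("sedation_gt4h", "logical"),
    row("vasoactives", "logical"),
    row("died", "logical"),
    row("died_in_ed", "logical"),
    row("ed_death_spo2_pct", "numeric", "%", min = 0, max = 100),
    row("ed_death_on_oxygen", "logical"),
    row("admitted", "logical"),
    row("los_days", "numeric", "days", min = 0, max = 365)
  )
  daily <- do.call(rbind, lapply(1:7, function(d) rbind(
    row(sprintf("d%d_spo2_min", d), "numeric", "%", min = 0, max = 100),
    row(sprintf("d%d_support", d), "enum",
        allowed = "IMV|CPAP|BIPAP|HFNC|SIMPLE_O2|NONE"),
    row(sprintf("d%d_interface", d), "enum",
        allowed = "NASAL|FULL_FACE|INVASIVE|NOT_APPLICABLE"),
    row(sprintf("d%d_fio2", d), "numeric", "fraction", min = 0.21, max = 1.0),
    row(sprintf("d%d_flow_lpm", d), "numeric", "L/min", min = 0, max = 80),
    row(sprintf("d%d_map_cmh2o", d), "numeric", "cmH2O", min = 0.1, max = 60)
  )))
  out <- rbind(fixed, daily)
  # only identity and structural fields are mandatory-valued; everything else
  # must be present as a column but may be blank per row
  out$required <- out$column %in% c("patient_id", "site_id")
  rownames(out) <- NULL
  out
}

#' Data dictionary for the site table
#'
#' @return data frame in the same shape as [patient_dictionary()].
#' @export
site_dictionary <- function() {
  data.frame(
    column = c("site_id", "country", "sdi_quintile", "gbd_region", "urban",
               "academic", "census_gt50", "picu", "intensivist_weekday"),
    type = c("id", "character", "enum", "enum", rep("logical", 5)),
    units = "",
    allowed = c("", "", paste(sdi_levels(), collapse = "|"),
                paste(gbd_regions(), collapse = "|"), rep("", 5)),
    required = c(TRUE, rep(FALSE, 8)),
    min = NA_real_, max = NA_real_,
    stringsAsFactors = FALSE
  )
}

parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "true", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "false", "F", "0")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  list(value = out, bad = bad)
}

parse_numeric <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  bad <- !is.na(x) & x != "" & is.na(v)
  list(value = v, bad = bad)
}

# Apply a dictionary to a character data frame. Returns list(data, problems):
# `data` holds typed columns with offending rows dropped, `problems` is a
# data frame (row, column, value, message) locating every rejected cell.
validate_table <- function(raw, dict, file = "<data>") {
  missing_cols <- setdiff(dict$column, names(raw))
  if (length(missing_cols)) {
    stop("schema error in ", file, ": missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  problems <- list()
  note <- function(rows, column, values, message) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<- data.frame(
        row = rows, column = column, value = values, message = message,
        stringsAsFactors = FALSE)
    }
  }
  typed <- raw
  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    x <- raw[[col]]
    x[is.na(x)] <- ""
    switch(dict$type[i],
      id = , character = {
        typed[[col]] <- ifelse(x == "", NA_character_, x)
        if (dict$required[i]) {
          note(which(x == ""), col, x[x == ""], "mandatory value is blank")
        }
      },
      enum = {
        levels <- strsplit(dict$allowed[i], "|", fixed = TRUE)[[1]]
        bad <- x != "" & !(x %in% levels)
        note(which(bad), col, x[bad],
             paste0("not an allowed level (", dict$allowed[i], ")"))
        typed[[col]] <- ifelse(x == "" | bad, NA_character_, x)
      },
      logical = {
        p <- parse_logical(x)
        note(which(p$bad), col, x[p$bad], "not interpretable as TRUE/FALSE")
        typed[[col]] <- p$value
      },
      numeric = {
        p <- parse_numeric(x)
        note(which(p$bad), col, x[p$bad], "not numeric")
        v <- p$value
        if (grepl("_fio2$", col)) {
          # percentage-entered FiO2 shim: 21..100 -> fraction
          pct <- !is.na(v) & v > 1 & v <= 100
          if (any(pct)) {
            message(sum(pct), " ", col,
                    " value(s) > 1 interpreted as percentages and divided by 100")
            v[pct] <- v[pct] / 100
          }
        }
        oob <- !is.na(v) & (v < dict$min[i] | v > dict$max[i])
        note(which(oob), col, x[oob],
             sprintf("outside bounds [%g, %g]", dict$min[i], dict$max[i]))
        v[oob] <- NA_real_
        typed[[col]] <- v
        p$bad <- p$bad | oob
      }
    )
  }
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), column = character(), value = character(),
               message = character(), stringsAsFactors = FALSE)
  keep <- !(seq_len(nrow(raw)) %in% problems$row)
  list(data = typed[keep, , drop = FALSE], problems = problems)
}

read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, colClasses = "character", na.strings = NULL,
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read and validate a patient table
#'
#' Every row becomes a validated patient record; rows violating a type,
#' range, or cross-field constraint are rejected and reported in the
#' \code{"problems"} attribute (columns row / column / value / message).
#' Columns beyond the dictionary are preserved untouched as passthrough.
#'
#' @param path CSV file of one row per patient.
#' @param dictionary column specification; defaults to [patient_dictionary()].
#' @return data frame of typed patient records with attributes
#'   \code{problems} (rejected-row diagnostics) and \code{passthrough}
#'   (names of preserved unknown columns).
#' @export
read_patients <- function(path, dictionary = patient_dictionary()) {
  raw <- read_raw_csv(path)
  res <- validate_table(raw, dictionary, file = path)
  pat <- res$data
  problems <- res$problems

  # cross-field invariants
  if (nrow(pat)) {
    flag <- function(cond, column, message) {
      bad <- which(!is.na(cond) & cond)
      if (length(bad)) {
        problems <<- rbind(problems, data.frame(
          row = bad, column = column, value = "", message = message,
          stringsAsFactors = FALSE))
        pat <<- pat[-bad, , drop = FALSE]
      }
    }
    flag(pat$died_in_ed %in% TRUE & !(pat$died %in% TRUE),
         "died_in_ed", "died_in_ed requires died")
    flag(!is.na(pat$los_days) &
           (!(pat$admitted %in% TRUE) | pat$died %in% TRUE),
         "los_days", "los_days only recorded for admitted survivors")
  }
  if (nrow(problems)) {
    warning(nrow(problems), " row-level problem(s) in ", path,
            "; offending rows rejected (see attr(x, 'problems'))",
            call. = FALSE)
  }
  rownames(pat) <- NULL
  attr(pat, "problems") <- problems
  attr(pat, "passthrough") <- setdiff(names(raw), dictionary$column)
  pat
}

#' Read and validate a site table
#'
#' @param path CSV of one row per site.
#' @return typed data frame with a \code{problems} attribute; duplicated
#'   \code{site_id}s are a schema error.
#' @export
read_sites <- function(path) {
  raw <- read_raw_csv(path)
  res <- validate_table(raw, site_dictionary(), file = path)
  if (anyDuplicated(res$data$site_id)) {
    stop("schema error in ", path, ": duplicated site_id: ",
         paste(unique(res$data$site_id[duplicated(res$data$site_id)]),
               collapse = ", "))
  }
  out <- res$data
  rownames(out) <- NULL
  attr(out, "problems") <- res$problems
  out
}

#' Read and validate site resource surveys
#'
#' Surveys are long-format CSV with columns \code{site_id}, \code{item},
#' \code{response}. Responses are 5-point Likert labels (never, rarely,
#' sometimes, often, always) mapped to levels 1..5; a blank response is
#' stored as missing, never as "never". Item identifiers outside the bundle
#' definition's survey vocabulary are a schema error.
#'
#' @param path survey CSV.
#' @param bundle_def a \code{bundle_definition}; fixes the item vocabulary.
#' @return data frame with columns \code{site_id}, \code{item},
#'   \code{response} (label or NA), \code{level} (integer 1..5 or NA), one
#'   row per (site, item); a \code{problems} attribute lists rejected rows.
#' @export
read_site_surveys <- function(path, bundle_def = default_bundle_definition()) {
  raw <- read_raw_csv(path)
  need <- c("site_id", "item", "response")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  vocab <- survey_vocabulary(bundle_def)
  unknown <- setdiff(unique(raw$item), vocab)
  if (length(unknown)) {
    stop("schema error in ", path, ": unknown resource item(s): ",
         paste(unknown, collapse = ", "))
  }
  lv <- likert_levels()
  resp <- raw$response
  resp[is.na(resp)] <- ""
  bad <- resp != "" & !(resp %in% names(lv))
  problems <- data.frame(row = which(bad),
                         column = rep("response", sum(bad)),
                         value = resp[bad],
                         message = rep("unknown Likert label", sum(bad)),
                         stringsAsFactors = FALSE)
  out <- data.frame(site_id = raw$site_id, item = raw$item,
                    response = ifelse(resp == "" | bad, NA_character_, resp),
                    stringsAsFactors = FALSE)
  out$level <- unname(lv[out$response])
  out <- out[!bad, , drop = FALSE]
  if (nrow(problems)) {
    warning(nrow(problems), " survey row(s) with unknown Likert labels rejected",
            call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  out
}

#' Write a table as canonical CSV
#'
#' Stable column order, empty fields for missing values, quoted strings;
#' round-trips through the matching reader.
#'
#' @param rows data frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("rows must be a data frame")
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}
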