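# End-to-end validation pipeline: read a cohort, resolve HER2, classify,
# index, group, and emit the report tables (class distribution,
# class-by-clinicopathology associations, group distribution, KM curve
# exports and log-rank results with Bonferroni flags).

cohort_col_types <- function() {
  list(
    patient_id = readr::col_character(),
    er_h = readr::col_double(), pgr_h = readr::col_double(),
    ck56_h = readr::col_double(), ck78_h = readr::col_double(),
    egfr_h = readr::col_double(), her2_ihc = readr::col_character(),
    her2_ish = readr::col_character(), her3_h = readr::col_double(),
    her4_h = readr::col_double(), p53_h = readr::col_double(),
    muc1_h = readr::col_double(),
    tubules = readr::col_integer(), pleomorphism = readr::col_integer(),
    mitosis = readr::col_integer(), size_cm = readr::col_double(),
    stage = readr::col_integer(),
    nodes_positive = readr::col_integer(), nodes_total = readr::col_integer(),
    time = readr::col_double(), event = readr::col_character()
  )
}

#' Read a cohort CSV
#'
#' Reads the fixed cohort schema (one row per patient): `patient_id`, the
#' ten marker columns (`er_h`, `pgr_h`, `ck56_h`, `ck78_h`, `egfr_h`,
#' `her2_ihc`, `her2_ish`, `her3_h`, `her4_h`, `p53_h`, `muc1_h`),
#' optionally the clinicopathology columns (`tubules`, `pleomorphism`,
#' `mitosis`, `size_cm`, `stage`, `nodes_positive`, `nodes_total`) and
#' outcome (`time`, `event`). Empty cells are missing. Strict numeric
#' parsing: malformed cells (e.g. decimal commas) raise an error naming
#' the row and column. Unknown columns are kept with a warning; missing
#' mandatory columns raise an error listing them.
#'
#' @param path Path to a comma-delimited UTF-8 file with a header row
#'   (BOM and CRLF line endings are tolerated).
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  mandatory <- c("patient_id", unname(marker_columns()), "her2_ihc")
  absent <- setdiff(mandatory, header)
  if (length(absent) > 0) {
    abort(paste0("Cohort file is missing mandatory column(s): ",
                 paste(absent, collapse = ", ")))
  }
  known <- cohort_col_types()
  unknown <- setdiff(header, names(known))
  if (length(unknown) > 0) {
    warn(paste0("Ignoring unknown column type(s), kept as text: ",
                paste(unknown, collapse = ", ")))
  }
  types <- do.call(readr::cols,
                   c(known[intersect(header, names(known))],
                     list(.default = readr::col_character())))
  out <- readr::read_csv(path, col_types = types, show_col_types = FALSE,
                         progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    p1 <- probs[1, ]
    abort(sprintf(
      "Cohort file failed strict parsing: %d problem(s); first at row %d, column %d (%s, got '%s').",
      nrow(probs), p1$row, p1$col, p1$expected, p1$actual))
  }
  out
}

#' Write a cohort (and its truth side-file)
#'
#' @param cohort Cohort tibble, possibly carrying truth columns.
#' @param path Output CSV path; truth columns, if present, go to a
#'   `<path>_truth.csv` side-file instead of the observable file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  truth_cols <- intersect(c("true_class", "true_index", "true_lp",
                            "true_group"), names(cohort))
  obs <- cohort[, setdiff(names(cohort), truth_cols)]
  readr::write_csv(obs, path)
  if (length(truth_cols) > 0) {
    readr::write_csv(cohort[, c("patient_id", truth_cols)],
                     paste0(sub("\\.csv$", "", path), "_truth.csv"))
  }
  invisible(path)
}

report_associations <- function(scored) {
  vars <- list(
    grade = npi_grade(scored$tubules, scored$pleomorphism, scored$mitosis),
    size = if_else(scored$size_cm < 1.5, "<1.5 cm", ">=1.5 cm"),
    stage = scored$stage
  )
  purrr::imap(vars, function(v, nm) {
    tab <- table(v, scored$class)
    res <- tryCatch(suppressWarnings(association(tab)),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble(variable = nm, chi2 = res$chi2, dof = res$dof, p = res$p,
           cramers_v = res$v, n = res$n)
  }) |> bind_rows()
}

#' Run the full validation workflow on a cohort
#'
#' Executes HER2 resolution, fuzzy classification, index computation,
#' prognostic-group assignment, Kaplan-Meier/log-rank survival comparisons
#' per class and per group, and class-by-clinicopathology association
#' tables. Patients excluded for equivocal HER2 are surfaced in the class
#' distribution and reconciliation, never silently dropped. Statistical
#' non-significance is not an error; classes with no patients are skipped
#' with a warning.
#'
#' @param cohort Cohort tibble (e.g. from [read_cohort()] or
#'   [generate()]).
#' @param cutoffs,rb,formulas Configuration (defaults:
#'   [default_cutoffs()], [default_rulebase()], [default_formulas()]).
#' @param her2_mode Equivocal-HER2 policy (see [resolve_her2()]).
#' @param alpha Family-wise significance level for the log-rank tests
#'   (default 0.01).
#' @param bonferroni Apply Bonferroni adjustment across the reported
#'   log-rank tests (default TRUE).
#'
#' @return An object of class `npi_report`: a list with tibbles
#'   `class_distribution`, `associations`, `group_distribution`,
#'   `km_curves`, `logrank`, `reconciliation` and a `meta` list.
#' @export
run_validation <- function(cohort,
                           cutoffs = default_cutoffs(),
                           rb = default_rulebase(),
                           formulas = default_formulas(),
                           her2_mode = c("exclude_equivocal", "ish_resolve"),
                           alpha = 0.01, bonferroni = TRUE) {
  her2_mode <- match.arg(her2_mode)
  cohort <- as_tibble(cohort)
  n_in <- nrow(cohort)
  inform(sprintf("stage=input rows=%d", n_in))

  classified <- classify_cohort(cohort, cutoffs, rb, her2_mode)
  dist <- class_distribution(classified)
  inform(sprintf("stage=classify classified=%d unclassified=%d excluded=%d",
                 sum(classified$class %in% npi_classes()),
                 sum(classified$class == "Unclassified"),
                 sum(classified$class == "Excluded")))

  scored <- filter(classified, .data$class %in% npi_classes())
  empty_classes <- setdiff(npi_classes(), unique(scored$class))
  if (length(empty_classes) > 0) {
    warn(paste0("No patients in class(es): ",
                paste(empty_classes, collapse = ", "),
                "; downstream stages skipped for them."))
  }

  have_clinpath <- all(clinpath_columns() %in% names(cohort)) &&
    nrow(scored) > 0
  associations <- if (have_clinpath) report_associations(scored) else tibble()

  grouped <- NULL
  group_distribution <- tibble()
  if (have_clinpath) {
    grouped <- scored |> compute_index(formulas) |> assign_group(formulas)
    all_groups <- purrr::imap(formulas, function(f, cl) {
      tibble(class = cl, prognostic_group = f$group_labels)
    }) |> bind_rows()
    group_distribution <- grouped |>
      count(.data$class, .data$prognostic_group) |>
      dplyr::right_join(all_groups, by = c("class", "prognostic_group")) |>
      mutate(n = dplyr::coalesce(.data$n, 0L),
             fraction = .data$n / max(1L, n_in)) |>
      arrange(match(.data$class, npi_classes()), .data$prognostic_group)
    inform(sprintf("stage=group grouped=%d", nrow(grouped)))
  }

  km_curves <- tibble()
  logrank <- tibble()
  have_surv <- all(c("time", "event") %in% names(cohort)) && nrow(scored) > 0
  if (have_surv) {
    enc <- bcss_encode(scored)
    km_cls <- km_estimate(enc, group = "class")
    km_curves <- mutate(km_cls$curve, panel = "class")
    lr <- purrr::map(list(
      list(panel = "class", data = enc, group = "class")), identity)
    if (!is.null(grouped)) {
      genc <- bcss_encode(grouped)
      km_grp <- km_estimate(genc, group = "prognostic_group")
      km_curves <- bind_rows(km_curves,
                             mutate(km_grp$curve, panel = "group"))
      per_class <- purrr::map(intersect(npi_classes(), unique(genc$class)),
                              function(cl) {
        list(panel = paste0("groups within ", cl),
             data = filter(genc, .data$class == cl),
             group = "prognostic_group")
      })
      lr <- c(lr, per_class)
    }
    logrank <- purrr::map(lr, function(spec) {
      res <- tryCatch(
        logrank_test(spec$data, spec$group),
        error = function(e) NULL)
      if (is.null(res)) {
        inform(sprintf("stage=logrank panel='%s' skipped", spec$panel))
        return(NULL)
      }
      tibble(panel = spec$panel, statistic = res$statistic,
             dof = res$dof, p = res$p, n = res$n)
    }) |> bind_rows()
    if (nrow(logrank) > 0) {
      logrank$significant <- if (bonferroni) {
        bonferroni_adjust(logrank$p, alpha)
      } else {
        logrank$p < alpha
      }
    }
    inform(sprintf("stage=survival km_rows=%d logrank_tests=%d",
                   nrow(km_curves), nrow(logrank)))
  }

  reconciliation <- tibble(
    outcome = c("classified", "unclassified", "excluded", "input"),
    n = c(sum(classified$class %in% npi_classes()),
          sum(classified$class == "Unclassified"),
          sum(classified$class == "Excluded"),
          n_in))
  stopifnot(sum(reconciliation$n[1:3]) == n_in)

  meta <- list(
    package = "npiplus",
    version = as.character(utils::packageVersion("npiplus")),
    n_input = n_in, her2_mode = her2_mode, alpha = alpha,
    bonferroni = bonferroni,
    config_hash = rlang::hash(list(cutoffs = as.data.frame(cutoffs),
                                   rb = rb, formulas = formulas)))

  structure(list(class_distribution = dist,
                 associations = associations,
                 group_distribution = group_distribution,
                 km_curves = km_curves,
                 logrank = logrank,
                 reconciliation = reconciliation,
                 classified = classified,
                 grouped = grouped,
                 meta = meta),
            class = "npi_report")
}

#' @export
print.npi_report <- function(x, ...) {
  cat("NPI+ validation report:", x$meta$n_input, "patients\n")
  cat("  classified:", x$reconciliation$n[1],
      " unclassified:", x$reconciliation$n[2],
      " excluded:", x$reconciliation$n[3], "\n")
  if (nrow(x$logrank) > 0) {
    cat("  log-rank tests:", nrow(x$logrank),
        " significant:", sum(x$logrank$significant), "\n")
  }
  invisible(x)
}

#' Write report artefacts to a directory
#'
#' Emits `class_distribution.csv`, `associations.csv`,
#' `group_distribution.csv`, `km_curves.csv` (columns time, survival,
#' at_risk, events, group, panel — ready for replotting), `logrank.csv`
#' and `run_meta.json`. Output is deterministic: rerunning on identical
#' inputs reproduces the files byte for byte.
#'
#' @param report An `npi_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "npi_report")) abort("`report` must be an npi_report.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$class_distribution,
                   file.path(dir, "class_distribution.csv"))
  readr::write_csv(report$associations, file.path(dir, "associations.csv"))
  readr::write_csv(report$group_distribution,
                   file.path(dir, "group_distribution.csv"))
  km <- report$km_curves
  if (nrow(km) > 0) {
    km <- select(km, "time", survival = "survival", at_risk = "n_risk",
                 events = "n_event", "group", "panel")
  }
  readr::write_csv(km, file.path(dir, "km_curves.csv"))
  readr::write_csv(report$logrank, file.path(dir, "logrank.csv"))
  jsonlite::write_json(report$meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
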