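# YAML round-tripping for the configurable pieces: cut-off tables and
# fuzzy rule bases. Both are plain structured text so a laboratory can
# edit cut-offs and rules without touching code.

#' Read and write cut-off tables
#'
#' @param cutoffs An `npi_cutoffs` table.
#' @param path File path for the YAML config.
#' @return `read_cutoffs()` returns an `npi_cutoffs` tibble;
#'   `write_cutoffs()` returns `path` invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  validate_cutoffs(cutoffs)
  entries <- purrr::pmap(cutoffs, function(marker, cutoff, policy) {
    list(marker = marker,
         cutoff = if (is.na(cutoff)) "resolve_her2" else cutoff,
         policy = policy)
  })
  yaml::write_yaml(list(cutoffs = entries), path)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  raw <- yaml::read_yaml(path)
  tab <- purrr::map(raw$cutoffs, function(e) {
    tibble(marker = e$marker,
           cutoff = if (identical(e$cutoff, "resolve_her2")) NA_real_
                    else as.numeric(e$cutoff),
           policy = e$policy)
  }) |> bind_rows()
  validate_cutoffs(tab)
  structure(tab, class = c("npi_cutoffs", class(tab)))
}

#' Read and write rule bases
#'
#' Serialises a rule base (rules with consequent, `marker:side`
#' antecedents and weight; global activation threshold; per-marker or
#' scalar membership width) to YAML. The round trip is lossless.
#'
#' @param rb An `npi_rulebase`.
#' @param path File path for the YAML config.
#' @return `read_rulebase()` returns an `npi_rulebase`; `write_rulebase()`
#'   returns `path` invisibly.
#' @export
write_rulebase <- function(rb, path) {
  if (!inherits(rb, "npi_rulebase")) abort("`rb` must be an npi_rulebase.")
  rules <- purrr::map(rb$rules, function(r) {
    list(consequent = r$consequent,
         antecedents = as.list(unclass(paste0(names(r$antecedents), ":",
                                              r$antecedents))),
         weight = r$weight)
  })
  width <- rb$membership_width
  width_field <- if (length(width) == 1 && is.null(names(width))) {
    unname(width)
  } else {
    as.list(width)
  }
  yaml::write_yaml(list(activation_threshold = rb$activation_threshold,
                        membership_width = width_field,
                        rules = rules), path)
  invisible(path)
}

#' @rdname write_rulebase
#' @export
read_rulebase <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- purrr::map(raw$rules, function(r) {
    parts <- strsplit(unlist(r$antecedents), ":", fixed = TRUE)
    ant <- setNames(purrr::map_chr(parts, 2), purrr::map_chr(parts, 1))
    fuzzy_rule(r$consequent, ant, r$weight %||% 1)
  })
  width <- raw$membership_width
  if (is.list(width)) width <- unlist(width)
  rulebase(rules, activation_threshold = raw$activation_threshold,
           membership_width = width)
}
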