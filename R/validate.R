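# Eligibility of catalog entries for phylogenetic analysis.
#
# Proteins lacking the catalytic triad, or whose protease domain is
# incomplete, are excluded from tree inference (their protease domains are
# under altered selective pressure and take misleading positions in the
# tree); catalog rows flagged as probable non-family members are excluded
# outright.  Declared catalog annotations take precedence over detection.

VALIDATION_REASONS <- c("TRUNCATED_PD", "MISSING_TRIAD_RESIDUE",
                        "NO_PD_DETECTED", "NOT_FAMILY_FLAG")

#' Validation / eligibility configuration
#'
#' @param truncation_frac a detected protease domain covering less than this
#'   fraction of the profile length counts as truncated (default 0.6).
#' @param triad_window half-width of the triad anchor window, in residues.
#' @param min_partial minimum length (residues) of a partial profile match
#'   considered when looking for truncated protease domains.
#' @export
validation_config <- function(truncation_frac = 0.6, triad_window = 3L,
                              min_partial = 20L) {
  stopifnot(truncation_frac > 0, truncation_frac <= 1)
  list(truncation_frac = truncation_frac, triad_window = triad_window,
       min_partial = min_partial)
}

#' Validate one catalog entry
#'
#' Applies the family's eligibility filters.  Order of precedence: the
#' catalog's `not_family` flag; a declared activity flag (with its recorded
#' reason); a declared architecture; finally sequence-based detection via
#' the profile scanner.  The result carries machine-readable reason codes;
#' an entry is eligible iff no reason applies.
#'
#' @param record one catalog row (data frame row or named list) with at
#'   least `id`; optionally `not_family`, `active`, `activity_reason`,
#'   `architecture`.
#' @param sequence amino-acid string (needed for the detection path).
#' @param profiles list of `deg_profile` (default [builtin_profiles()]).
#' @param config a [validation_config()].
#' @return list of class `deg_validation`: `id`, `eligible`, `reasons`.
#' @export
validate_entry <- function(record, sequence = NULL,
                           profiles = builtin_profiles(),
                           config = validation_config()) {
  rec <- as.list(record)
  reasons <- character(0)
  decided <- FALSE

  if (isTRUE(as.logical(rec$not_family))) {
    reasons <- c(reasons, "NOT_FAMILY_FLAG")
    decided <- TRUE
  }
  act <- rec$active
  if (!is.null(act) && !is.na(act)) {
    decided <- TRUE
    if (!isTRUE(as.logical(act))) {
      code <- rec$activity_reason %||% ""
      if (!code %in% VALIDATION_REASONS) code <- "MISSING_TRIAD_RESIDUE"
      reasons <- c(reasons, code)
    }
  } else if (!decided && !is.null(rec$architecture) &&
             nzchar(rec$architecture %||% "")) {
    a <- parse_architecture(rec$architecture)
    decided <- TRUE
    if (count_domains(a, "PD") == 0L) {
      reasons <- c(reasons,
                   if (count_domains(a, "PD_ia") > 0L)
                     "MISSING_TRIAD_RESIDUE" else "NO_PD_DETECTED")
    }
  }

  if (!decided) {
    if (is.null(sequence))
      stop("record '", rec$id %||% "?",
           "' has neither declared annotations nor a sequence to validate")
    reasons <- c(reasons, detect_pd_reasons(sequence, profiles, config))
  }

  structure(list(id = rec$id %||% NA_character_,
                 eligible = length(reasons) == 0L,
                 reasons = unique(reasons)),
            class = "deg_validation")
}

# Sequence-based eligibility: full-window PD hit with complete triad is
# eligible; a partial (end-truncated) profile match below the coverage
# threshold is a truncated protease domain; no match at all means no
# protease domain was detected.
detect_pd_reasons <- function(sequence, profiles, config) {
  kinds <- vapply(profiles, `[[`, "", "kind")
  if (!any(kinds == "PD")) stop("profile list has no PD profile")
  pd <- profiles[[which(kinds == "PD")[1L]]]
  codes <- seq_to_codes(sequence)

  if (length(codes) >= pd$length) {
    sc <- profile_window_scores(codes, pd)
    if (any(sc >= pd$threshold)) {
      s <- which.max(sc)
      tri <- check_triad(sequence, c(s, s + pd$length - 1L), pd,
                         config$triad_window)
      return(if (tri$complete) character(0) else "MISSING_TRIAD_RESIDUE")
    }
  }
  cov <- best_partial_pd_coverage(codes, pd, config$min_partial)
  if (is.na(cov)) "NO_PD_DETECTED"
  else if (cov < config$truncation_frac) "TRUNCATED_PD"
  else "NO_PD_DETECTED"   # long partial match that still failed threshold
}

# Best coverage fraction over prefix/suffix sub-profiles that score at or
# above the proportionally scaled threshold; NA if none does.
best_partial_pd_coverage <- function(codes, pd, min_partial) {
  n <- length(codes)
  L <- pd$length
  pssmX <- cbind(pd$pssm, X = 0)
  best <- NA_real_
  lens <- seq(min(min_partial, L), min(n, L - 1L))
  for (l in lens) {
    thr <- pd$threshold * l / L
    # profile prefix of length l anywhere in the sequence
    for (s in seq_len(n - l + 1L)) {
      pre <- sum(pssmX[cbind(seq_len(l), codes[s:(s + l - 1L)])])
      suf <- sum(pssmX[cbind((L - l + 1L):L, codes[s:(s + l - 1L)])])
      if (max(pre, suf) >= thr)
        best <- max(best, l / L, na.rm = TRUE)
    }
  }
  best
}

#' @export
print.deg_validation <- function(x, ...) {
  cat(x$id, if (x$eligible) "eligible"
      else paste("ineligible:", paste(x$reasons, collapse = ", ")), "\n")
  invisible(x)
}

#' Validate every record of a catalog
#'
#' @param catalog a `deg_catalog`.
#' @param sequences optional named character vector of sequences (detection
#'   path for records without declared annotations).
#' @inheritParams validate_entry
#' @return data frame: `id`, `species`, `eligible`, `reasons`
#'   (comma-separated codes).
#' @examples
#' cat5 <- load_catalog(degphylo_example("catalog_plants.tsv"),
#'                      degphylo_example("registry_plants.tsv"))
#' v <- validate_catalog(cat5)
#' sum(v$eligible[v$species == "At"])   # 14 potentially active in A. thaliana
#' @export
validate_catalog <- function(catalog, sequences = NULL,
                             profiles = builtin_profiles(),
                             config = validation_config()) {
  stopifnot(inherits(catalog, "deg_catalog"))
  rec <- catalog$records
  res <- lapply(seq_len(nrow(rec)), function(i) {
    seq_i <- if (rec$id[i] %in% names(sequences)) sequences[[rec$id[i]]]
    validate_entry(rec[i, ], sequence = seq_i,
                   profiles = profiles, config = config)
  })
  data.frame(id = rec$id, species = rec$species,
             eligible = vapply(res, `[[`, TRUE, "eligible"),
             reasons = vapply(res, function(r)
               paste(r$reasons, collapse = ","), ""))
}
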