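# Position-specific scoring profiles for domain detection.
#
# A declared, simplified profile scanner: each domain kind is represented by
# a log-odds PSSM built from a small seed alignment, scanned along the query
# by a sliding window.  External annotations (declared architectures in the
# catalog) always override detection.  Protease-domain (PD) profiles carry
# anchor positions for the His/Asp/Ser catalytic triad.

seq_to_codes <- function(sequence) {
  codes <- match(strsplit(sequence, "")[[1L]], AA_ALPHABET21)
  if (anyNA(codes))
    stop("sequence contains characters outside the amino-acid alphabet + X")
  codes
}

#' Build a domain profile from seed sequences
#'
#' Seed sequences must be pre-aligned and gap-free (equal length).  The PSSM
#' holds log2 odds of the position-specific residue frequency (with
#' pseudocounts proportional to the background) against the background
#' distribution; an X in the query scores 0 at every position.  The score
#' threshold defaults to half of the maximum attainable window score, a
#' calibration at which shuffled sequences essentially never reach threshold
#' (tested at a false-positive rate below 1%).
#'
#' @param seeds character vector of equal-length amino-acid sequences.
#' @param kind domain token the profile detects (`"PD"`, `"PDZ"`, ...).
#' @param anchors for PD profiles, named integer vector of 1-based positions
#'   of the catalytic His, Asp and Ser within the profile,
#'   e.g. `c(H = 12, D = 29, S = 48)`.
#' @param background background residue frequencies (default WAG equilibrium).
#' @param pseudocount total pseudocount mass per column.
#' @param threshold_frac threshold as a fraction of the maximum window score.
#' @return an object of class `deg_profile`.
#' @export
build_profile <- function(seeds, kind, anchors = NULL,
                          background = wag_model()$freqs,
                          pseudocount = 1, threshold_frac = 0.5) {
  stopifnot(length(seeds) >= 1L, length(unique(nchar(seeds))) == 1L)
  L <- nchar(seeds[[1L]])
  counts <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  for (s in seeds) {
    codes <- seq_to_codes(s)
    if (any(codes > 20L)) stop("seed sequences must not contain X")
    counts[cbind(seq_len(L), codes)] <- counts[cbind(seq_len(L), codes)] + 1
  }
  freq <- (counts + pseudocount * rep(background, each = L)) /
    (length(seeds) + pseudocount)
  pssm <- log2(freq / rep(background, each = L))
  if (!is.null(anchors)) {
    stopifnot(all(names(anchors) %in% c("H", "D", "S")),
              all(anchors >= 1L & anchors <= L))
    anchors <- anchors[c("H", "D", "S")]
  }
  consensus <- paste(AA20[max.col(pssm, ties.method = "first")], collapse = "")
  structure(list(kind = kind, pssm = pssm, length = L,
                 threshold = threshold_frac * sum(apply(pssm, 1L, max)),
                 anchors = anchors, consensus = consensus),
            class = "deg_profile")
}

#' @export
print.deg_profile <- function(x, ...) {
  cat("Domain profile [", x$kind, "]: length ", x$length,
      ", threshold ", round(x$threshold, 1), sep = "")
  if (!is.null(x$anchors))
    cat(", triad anchors ", paste(names(x$anchors), x$anchors, sep = ":",
                                  collapse = " "), sep = "")
  cat("\n")
  invisible(x)
}

# Seed alignments for the bundled protease-domain and PDZ profiles.  The PD
# seeds carry the His-Asp-Ser triad at fixed anchor positions (12/29/48);
# the remaining positions vary across seeds as divergent family members do.
PD_SEEDS <- c(
  "GSGFIVSEDGYHILTNAHVVGNAKEIRVDGKEYPAKVVARDPKTDLASGGPLLNLDGEVI",
  "GSGFIVAKDGYHILTNAHVVGNATELRVDGKEYEAKVVARDPKSDIASGGPLLNLDGQVI",
  "GSGVIVSEDGLHILTNAHVIGNAKEIKVDGHEYPAKVIAKDPKTDLASGGPLINLEGEVI",
  "GAGFIVSEDGYHVLTNAHVVDNAKEIRVELKEYPAKVVARDPKTDLASGSPLLNIDGEVI")
PD_ANCHORS <- c(H = 12L, D = 29L, S = 48L)

PDZ_SEEDS <- c(
  "GVLVTQVLPNSPAEKAGLKAGDVILAVNGKPVKSAS",
  "GVLVSQVLPNSPADKAGIKAGDVITAVNGKPVTSAS",
  "GVIVTEVLPNSEAEKAGLKEGDVILAVDGKPVKSAD",
  "GALVAQVLENSPAEKAGLKAGDVILAVNGKSVKSAE")

#' Bundled profiles for the Deg/HtrA family
#'
#' @return list of `deg_profile` objects (PD with triad anchors, PDZ).
#' @export
builtin_profiles <- function() {
  list(PD = build_profile(PD_SEEDS, "PD", anchors = PD_ANCHORS),
       PDZ = build_profile(PDZ_SEEDS, "PDZ"))
}

#' Scan a sequence for domain hits
#'
#' Slides each profile along the sequence; windows scoring at or above the
#' profile threshold are candidate hits, resolved greedily by descending
#' score into a non-overlapping set reported in coordinate order.
#'
#' @param sequence amino-acid string.
#' @param profiles list of `deg_profile` objects.
#' @return data frame with columns `kind`, `start`, `end` (1-based,
#'   inclusive), `score`.
#' @export
detect_domains <- function(sequence, profiles) {
  if (length(profiles) == 0L) stop("empty profile list")
  stopifnot(all(vapply(profiles, inherits, TRUE, "deg_profile")))
  codes <- seq_to_codes(sequence)
  if (length(codes) < min(vapply(profiles, `[[`, 0L, "length")))
    stop("sequence shorter than the shortest profile")
  hits <- list()
  for (p in profiles) {
    sc <- profile_window_scores(codes, p)
    keep <- which(sc >= p$threshold)
    if (length(keep))
      hits[[length(hits) + 1L]] <- data.frame(
        kind = p$kind, start = keep, end = keep + p$length - 1L,
        score = sc[keep])
  }
  if (!length(hits))
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), score = numeric()))
  h <- do.call(rbind, hits)
  h <- h[order(-h$score, h$start, h$kind), , drop = FALSE]
  taken <- integer(0)
  sel <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    span <- h$start[i]:h$end[i]
    if (!any(span %in% taken)) {
      sel[i] <- TRUE
      taken <- c(taken, span)
    }
  }
  h <- h[sel, , drop = FALSE]
  h <- h[order(h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

profile_window_scores <- function(codes, profile) {
  L <- profile$length
  n <- length(codes)
  if (n < L) return(numeric(0))
  pssmX <- cbind(profile$pssm, X = 0)    # X scores 0 everywhere
  starts <- seq_len(n - L + 1L)
  vapply(starts, function(s)
    sum(pssmX[cbind(seq_len(L), codes[s:(s + L - 1L)])]), 0)
}

#' Check the His-Asp-Ser catalytic triad within a protease-domain hit
#'
#' Each triad residue is accepted if it occurs within a +/- `window` residue
#' neighbourhood of its anchored position (the profile anchor offset mapped
#' onto the hit span).
#'
#' @param sequence amino-acid string.
#' @param pd_span integer vector `c(start, end)` (1-based, inclusive) of the
#'   PD hit.
#' @param profile the PD `deg_profile` (must carry triad anchors).
#' @param window neighbourhood half-width in residues (default 3).
#' @return list of class `deg_triad`: `has_his`, `has_asp`, `has_ser`,
#'   `positions` (found positions or NA), `complete`.
#' @export
check_triad <- function(sequence, pd_span, profile, window = 3L) {
  stopifnot(inherits(profile, "deg_profile"), !is.null(profile$anchors))
  n <- nchar(sequence)
  if (pd_span[1L] < 1L || pd_span[2L] > n || pd_span[1L] > pd_span[2L])
    stop("pd_span outside sequence")
  chars <- strsplit(sequence, "")[[1L]]
  found <- vapply(names(profile$anchors), function(res) {
    pos <- pd_span[1L] + profile$anchors[[res]] - 1L
    lo <- max(1L, as.integer(pos - window))
    hi <- min(n, as.integer(pos + window))
    w <- which(chars[lo:hi] == res)
    if (length(w)) as.integer(lo + w[1L] - 1L) else NA_integer_
  }, 0L)
  res <- list(has_his = !is.na(found[["H"]]),
              has_asp = !is.na(found[["D"]]),
              has_ser = !is.na(found[["S"]]),
              positions = found)
  res$complete <- res$has_his && res$has_asp && res$has_ser
  class(res) <- "deg_triad"
  res
}

#' @export
print.deg_triad <- function(x, ...) {
  cat("Catalytic triad:",
      if (x$complete) "complete (His, Asp, Ser)" else paste0(
        "incomplete (missing ",
        paste(c("His", "Asp", "Ser")[!c(x$has_his, x$has_asp, x$has_ser)],
              collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Annotate the domain architecture of a sequence
#'
#' Runs [detect_domains()] and, for each PD hit, [check_triad()]; PD hits
#' with an incomplete triad are labelled `PD_ia` (a degenerated protease
#' domain with a mutated catalytic triad).
#'
#' @inheritParams detect_domains
#' @param window triad window, see [check_triad()].
#' @return list with `architecture` (a `deg_architecture` or NULL if no hit),
#'   `hits` (data frame, `kind` rewritten to `PD_ia` where applicable) and
#'   `triads` (list of `deg_triad` per PD hit, by hit row).
#' @export
annotate_architecture <- function(sequence, profiles = builtin_profiles(),
                                  window = 3L) {
  hits <- detect_domains(sequence, profiles)
  triads <- list()
  pd <- vapply(profiles, `[[`, "", "kind") == "PD"
  pd_profile <- if (any(pd)) profiles[[which(pd)[1L]]] else NULL
  if (!is.null(pd_profile)) {
    for (i in which(hits$kind == "PD")) {
      tri <- check_triad(sequence, c(hits$start[i], hits$end[i]),
                         pd_profile, window)
      triads[[as.character(i)]] <- tri
      if (!tri$complete) hits$kind[i] <- "PD_ia"
    }
  }
  arch <- if (nrow(hits)) structure(hits$kind, class = "deg_architecture")
          else NULL
  list(architecture = arch, hits = hits, triads = triads)
}

#' Write / read profiles as TSV score tables with a manifest
#'
#' Each profile is stored as one TSV (rows = positions, columns = residues);
#' `manifest.tsv` lists kind, file, threshold and triad anchors.
#'
#' @param profiles list of `deg_profile`.
#' @param dir directory (created if needed).
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(kind = character(), file = character(),
                    threshold = character(), anchors = character())
  for (p in profiles) {
    f <- paste0("profile_", p$kind, ".tsv")
    write_tsv(as.data.frame(p$pssm), file.path(dir, f))
    anch <- if (is.null(p$anchors)) "" else
      paste(names(p$anchors), p$anchors, sep = ":", collapse = ",")
    man <- rbind(man, data.frame(kind = p$kind, file = f,
                                 threshold = format(p$threshold, digits = 12),
                                 anchors = anch))
  }
  write_tsv(man, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(dir) {
  man <- read_tsv_checked(file.path(dir, "manifest.tsv"),
                          c("kind", "file", "threshold", "anchors"))
  profiles <- list()
  for (i in seq_len(nrow(man))) {
    pssm <- as.matrix(read.delim(file.path(dir, man$file[i]), sep = "\t",
                                 check.names = FALSE))
    colnames(pssm) <- AA20
    anchors <- NULL
    if (nzchar(man$anchors[i])) {
      kv <- strsplit(strsplit(man$anchors[i], ",")[[1L]], ":")
      anchors <- setNames(vapply(kv, function(x) as.integer(x[2L]), 0L),
                          vapply(kv, `[`, "", 1L))
    }
    consensus <- paste(AA20[max.col(pssm, ties.method = "first")],
                       collapse = "")
    profiles[[man$kind[i]]] <- structure(
      list(kind = man$kind[i], pssm = pssm, length = nrow(pssm),
           threshold = as.numeric(man$threshold[i]), anchors = anchors,
           consensus = consensus),
      class = "deg_profile")
  }
  profiles
}
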