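# Conservation matrix and core set.
#
# The species x group matrix counts family members per ortholog group and
# species (outgroup excluded); the core set is the groups present in every
# species, in the lowest copy number observed.

#' Build the conservation matrix
#'
#' One row per ortholog group (like and group-like groups included), one
#' column per non-outgroup registry species; cells count group members.
#'
#' @param groups a `deg_groups` (from [assign_ortholog_groups()] or
#'   [catalog_groups()]).
#' @param registry a `deg_registry` (or a `deg_catalog`).
#' @param names optional named vector id -> proposed name (used to render
#'   isoform labels, e.g. `"9.1, 9.2"`).
#' @param include_outgroup keep outgroup species as columns (default FALSE).
#' @return integer matrix of class `deg_consmat` with attribute `"isoforms"`.
#' @export
build_conservation_matrix <- function(groups, registry, names = NULL,
                                      include_outgroup = FALSE) {
  if (inherits(registry, "deg_catalog")) registry <- registry$registry
  asn <- groups$assignment
  species <- registry$code
  if (!include_outgroup) species <- species[!registry$is_outgroup]
  gnames <- unique(asn$group)
  M <- matrix(0L, length(gnames), length(species),
              dimnames = list(gnames, species))
  iso <- matrix("", length(gnames), length(species),
                dimnames = list(gnames, species))
  for (g in gnames) for (s in species) {
    sel <- asn$group == g & asn$species == s
    M[g, s] <- sum(sel)
    if (!is.null(names) && sum(sel) > 1L) {
      nm <- sort(names[asn$id[sel]])
      iso[g, s] <- paste(sub(paste0("^", s), "", nm), collapse = ", ")
    }
  }
  structure(M, isoforms = iso, class = "deg_consmat")
}

#' Derive ortholog groups from a catalog's declared annotations
#'
#' Catalog-only mode: uses the `group` column (records with an empty group
#' or the non-family flag are skipped).  Status is inferred from the group
#' name: groups containing the configured group-like suffix are
#' `group_like`, groups matching the like prefix are `like`, all others
#' `anchored`.
#'
#' @param catalog a `deg_catalog`.
#' @param config a [nomenclature_config()].
#' @return a `deg_groups`.
#' @export
catalog_groups <- function(catalog, config = nomenclature_config()) {
  rec <- catalog$records
  keep <- nzchar(rec$group) & !rec$not_family
  rec <- rec[keep, , drop = FALSE]
  if (!nrow(rec)) stop("catalog declares no ortholog groups")
  ref_code <- catalog$registry$code[catalog$registry$is_reference_anchor]
  anchored_groups <- unique(rec$group[rec$species == ref_code])
  status <- ifelse(grepl(config$grouplike_suffix, rec$group, fixed = TRUE),
                   "group_like",
                   ifelse(rec$group %in% anchored_groups,
                          "anchored", "like"))
  asn <- data.frame(id = rec$id, species = rec$species, group = rec$group,
                    status = status, support = NA_real_,
                    anchor_dist = NA_real_, row.names = NULL)
  gsum <- aggregate(cbind(n_members = rep(1L, nrow(asn))) ~ group + status,
                    data = asn, FUN = sum)
  ref <- catalog$registry$code[catalog$registry$is_reference_anchor]
  structure(list(assignment = asn, groups = gsum, reference_species = ref,
                 config = config),
            class = "deg_groups")
}

#' @export
print.deg_consmat <- function(x, ...) {
  cat("Conservation matrix:", nrow(x), "groups x", ncol(x), "species\n")
  print(format(x))
  invisible(x)
}

#' @export
format.deg_consmat <- function(x, ...) {
  iso <- attr(x, "isoforms")
  out <- matrix("-", nrow(x), ncol(x), dimnames = dimnames(x))
  out[x == 1L] <- "+"
  multi <- which(unclass(x) > 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(multi))) {
    i <- multi[k, 1L]; j <- multi[k, 2L]
    out[i, j] <- if (!is.null(iso) && nzchar(iso[i, j])) iso[i, j]
                 else as.character(x[i, j])
  }
  out
}

#' Extract the conserved core set
#'
#' Core groups have at least one member in every species of the matrix; the
#' per-group minimum copy number is the count the hypothetical minimal cell
#' would need.  Row order is preserved.
#'
#' @param m a `deg_consmat` (or plain count matrix, groups x species).
#' @return object of class `deg_coreset`: data frame `group`, `min_copies`.
#' @examples
#' cat5 <- load_catalog(degphylo_example("catalog_plants.tsv"),
#'                      degphylo_example("registry_plants.tsv"))
#' m <- build_conservation_matrix(catalog_groups(cat5), cat5)
#' compute_core_set(m)   # the eight-member core set
#' @export
compute_core_set <- function(m) {
  M <- unclass(m)
  if (ncol(M) < 1L) stop("conservation matrix has no species")
  core <- rownames(M)[apply(M >= 1L, 1L, all)]
  res <- data.frame(group = core,
                    min_copies = apply(M[core, , drop = FALSE], 1L, min),
                    row.names = NULL)
  class(res) <- c("deg_coreset", "data.frame")
  res
}

#' @export
print.deg_coreset <- function(x, ...) {
  cat("Core set:", nrow(x), "ortholog groups present in every species\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Per-species duplication report
#'
#' Lists, for each species, the groups present in two or more copies.
#'
#' @param m a `deg_consmat`.
#' @return named list, species -> named integer vector of multi-copy
#'   groups.
#' @export
duplication_report <- function(m) {
  M <- unclass(m)
  out <- lapply(colnames(M), function(s) {
    v <- setNames(M[, s], rownames(M))
    v[v >= 2L]
  })
  names(out) <- colnames(M)
  out
}
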