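# Reference-anchored ortholog groups and standardized names.
#
# The naming engine codifies how the family tree is read: root on the
# outgroup, take every clade with bootstrap support above a threshold, and
# give each non-reference protein the name of the reference-species anchor
# in the smallest supported clade that contains both.  Proteins outside all
# anchored supported clades become numbered "-like" members; proteins whose
# smallest supported anchored clade mixes several anchor names cannot be
# placed in a single group and are reported as "group-like" attached to the
# nearest anchor's name.

#' Nomenclature configuration
#'
#' @param support_strong,support_weak reporting thresholds (%) for strongly
#'   / weakly supported clades (defaults 90 and 70; comparisons are strict,
#'   i.e. support must exceed the threshold).
#' @param assignment_threshold minimum support (%) a clade must exceed to
#'   delimit ortholog groups (default 70).
#' @param reference_species species code of the nomenclature anchor; NULL
#'   uses the registry's reference-anchor species.
#' @param base_prefix family name stem used for constructed names
#'   (default `"Deg"`).
#' @param like_prefix name stem for members outside all anchored clades
#'   (default `"Deg-like"`).
#' @param grouplike_suffix suffix for ambiguous members (default
#'   `"group-like"`).
#' @export
nomenclature_config <- function(support_strong = 90, support_weak = 70,
                                assignment_threshold = 70,
                                reference_species = NULL,
                                base_prefix = "Deg",
                                like_prefix = "Deg-like",
                                grouplike_suffix = "group-like") {
  stopifnot(support_weak >= 0, support_weak <= support_strong,
            support_strong <= 100)
  list(support_strong = support_strong, support_weak = support_weak,
       assignment_threshold = assignment_threshold,
       reference_species = reference_species, base_prefix = base_prefix,
       like_prefix = like_prefix, grouplike_suffix = grouplike_suffix)
}

# capture split -> node-label mapping before re-rooting so supports can be
# transferred onto the re-rooted tree by bipartition identity
label_splits <- function(tree) {
  if (is.null(tree$node.label)) return(character(0))
  all_tips <- sort(tree$tip.label)
  parts <- ape::prop.part(ape::unroot(tree))
  labs <- attr(parts, "labels")
  u <- ape::unroot(tree)
  out <- character(0)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (min(length(side), length(all_tips) - length(side)) < 2L) next
    lab <- u$node.label[k]
    if (!is.null(lab) && nzchar(lab))
      out[canonical_split(side, all_tips)] <- lab
  }
  out
}

apply_split_labels <- function(tree, table) {
  all_tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  node_lab <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    if (min(length(side), length(all_tips) - length(side)) < 2L) next
    key <- canonical_split(side, all_tips)
    if (key %in% names(table)) node_lab[k] <- table[[key]]
  }
  tree$node.label <- node_lab
  tree
}

#' Root a tree on its outgroup
#'
#' If the outgroup is monophyletic in the unrooted tree, the root is placed
#' on its stem edge with the stem length split evenly.  Otherwise the root
#' goes on the edge that separates as many outgroup leaves from as many
#' ingroup leaves as possible (exhaustive edge scan), with a warning.
#' Bootstrap supports (node labels) are transferred by bipartition identity
#' and stay attached to the same edges.
#'
#' @param tree a `phylo` (rooted input is unrooted first).
#' @param outgroup_ids non-empty subset of the leaf labels.
#' @return rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_ids) {
  if (length(outgroup_ids) == 0L) stop("empty outgroup set")
  missing <- setdiff(outgroup_ids, tree$tip.label)
  if (length(missing))
    stop("outgroup ids absent from tree: ", paste(missing, collapse = ", "))
  supports <- label_splits(tree)
  u <- ape::unroot(tree)
  side <- outgroup_side(u, outgroup_ids)
  rooted <- ape::root(u, outgroup = side, resolve.root = TRUE,
                      edgelabel = TRUE)
  # split the stem length evenly across the two root edges
  root_node <- ape::Ntip(rooted) + 1L
  re <- which(rooted$edge[, 1L] == root_node)
  if (length(re) == 2L) {
    stem <- sum(rooted$edge.length[re])
    rooted$edge.length[re] <- stem / 2
  }
  if (length(supports)) rooted <- apply_split_labels(rooted, supports)
  rooted
}

# the set of tips on the rooting side: the outgroup itself when
# monophyletic, else the side of the best-separating edge
outgroup_side <- function(u, outgroup_ids) {
  all_tips <- u$tip.label
  og <- intersect(all_tips, outgroup_ids)
  if (length(og) == 1L || length(og) == length(all_tips) - 1L)
    return(og)
  sides <- tree_edge_sides(u)
  for (s in sides)
    if (setequal(s, og) || setequal(setdiff(all_tips, s), og)) return(og)
  # non-monophyletic: maximise correctly separated leaves over all edges
  best <- NULL; best_score <- -1L
  for (s in sides) {
    comp <- setdiff(all_tips, s)
    # outgroup taken to be on s: correctly placed = og in s + ingroup in comp
    sc_s <- length(intersect(s, og)) + length(setdiff(comp, og))
    sc_c <- length(intersect(comp, og)) + length(setdiff(s, og))
    sc <- max(sc_s, sc_c)
    if (sc > best_score) {
      best_score <- sc
      best <- if (sc_s >= sc_c) s else comp
    }
  }
  warning("outgroup is not monophyletic; rooting on the best-separating ",
          "edge")
  best
}

# tip sets below each edge of an unrooted tree (child side)
tree_edge_sides <- function(u) {
  nt <- ape::Ntip(u)
  parts <- ape::prop.part(u)
  labs <- attr(parts, "labels")
  sides <- lapply(parts[-1L], function(p) labs[p])   # drop root "clade"
  tips <- as.list(u$tip.label)
  c(sides, tips)
}

#' Extract supported clades
#'
#' All clades of a rooted tree whose subtending edge has bootstrap support
#' strictly greater than `threshold`, largest first.
#'
#' @param tree rooted `phylo` with numeric node labels (supports).
#' @param threshold support threshold in percent.
#' @return list of leaf-label vectors, sorted by size descending, with a
#'   `"support"` attribute.
#' @export
supported_clades <- function(tree, threshold) {
  if (is.null(tree$node.label) || !any(nzchar(tree$node.label)))
    stop("tree carries no support values")
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  n_tips <- length(labs)
  out <- list(); sup <- numeric(0)
  for (k in seq_along(parts)) {
    if (k == 1L) next                       # root clade: no subtending edge
    s <- suppressWarnings(as.numeric(tree$node.label[k]))
    # a clade whose complement is a single leaf is a trivial bipartition,
    # present in every replicate: full support by definition
    if (is.na(s) && n_tips - length(parts[[k]]) <= 1L) s <- 100
    if (is.na(s)) next
    if (s > threshold) {
      out[[length(out) + 1L]] <- labs[parts[[k]]]
      sup <- c(sup, s)
    }
  }
  ord <- order(-vapply(out, length, 0L))
  out <- out[ord]
  attr(out, "support") <- sup[ord]
  out
}

#' Exclude probable non-members and distant relatives
#'
#' Mirrors the pre-final-tree clean-up: records carrying the catalog's
#' non-family flag are removed, as are leaves that do not cluster (at the
#' assignment threshold) with any other analysed family member and so
#' appear to be only distant relatives.  Excluded records are reported for
#' "-like" naming.
#'
#' @param tree tree over the initially eligible records (with supports).
#' @param catalog a `deg_catalog`.
#' @param config a [nomenclature_config()].
#' @return list with `retained` (ids) and `excluded` (data frame `id`,
#'   `reason`).
#' @export
exclude_distant_relatives <- function(tree, catalog,
                                      config = nomenclature_config()) {
  rec <- catalog$records
  reg <- catalog$registry
  tips <- tree$tip.label
  outgroup <- intersect(
    tips, rec$id[rec$species %in% reg$code[reg$is_outgroup]])
  flagged <- intersect(tips, rec$id[rec$not_family])
  clades <- supported_clades(tree, config$assignment_threshold)
  clustered <- unique(unlist(clades[vapply(clades, length, 0L) >= 2L]))
  # outgroup leaves are distant by design and never excluded by rule (ii)
  lonely <- setdiff(tips, c(clustered, flagged, outgroup))
  excluded <- rbind(
    if (length(flagged)) data.frame(id = flagged, reason = "NOT_FAMILY_FLAG"),
    if (length(lonely)) data.frame(id = lonely, reason = "DISTANT_RELATIVE"))
  if (is.null(excluded))
    excluded <- data.frame(id = character(), reason = character())
  list(retained = setdiff(tips, excluded$id), excluded = excluded)
}

#' Assign reference-anchored ortholog groups
#'
#' Every reference-species leaf is an anchor carrying its established name.
#' Each other (non-outgroup) leaf joins the anchor group of the smallest
#' supported clade (support > `assignment_threshold`) containing the leaf
#' and at least one anchor.  If that clade mixes several anchor names the
#' leaf is `group_like`, attached to the name of its nearest anchor in the
#' clade (patristic distance, lexicographic tie-break).  Leaves in no
#' anchored supported clade form numbered `like` groups: leaves sharing a
#' maximal all-unanchored supported clade are grouped together, numbered in
#' tip order.
#'
#' @param tree rooted tree with supports (see [root_with_outgroup()],
#'   [bootstrap_supports()]).
#' @param catalog a `deg_catalog` whose records cover the tree leaves;
#'   reference-species records must carry `anchor_name`.
#' @param config a [nomenclature_config()].
#' @return object of class `deg_groups`: list with `assignment` (data frame
#'   `id`, `species`, `group`, `status`, `support`, `anchor_dist`), `groups`
#'   (per-group summary), `reference_species`, `config`.
#' @export
assign_ortholog_groups <- function(tree, catalog,
                                   config = nomenclature_config()) {
  rec <- catalog$records
  reg <- catalog$registry
  ref <- config$reference_species %||% reg$code[reg$is_reference_anchor]
  tips <- tree$tip.label
  sp <- rec$species[match(tips, rec$id)]
  if (anyNA(sp)) stop("tree leaves missing from catalog: ",
                      paste(tips[is.na(sp)], collapse = ", "))
  outgroup_sp <- reg$code[reg$is_outgroup]
  is_out <- sp %in% outgroup_sp
  anchors <- tips[sp == ref]
  if (!length(anchors)) stop("no reference-species anchors in the tree")
  anchor_name <- rec$anchor_name[match(anchors, rec$id)]
  if (any(!nzchar(anchor_name)))
    stop("reference-species records must carry anchor_name")
  names(anchor_name) <- anchors

  clades <- supported_clades(tree, config$assignment_threshold)
  csize <- vapply(clades, length, 0L)
  csupport <- attr(clades, "support")
  D <- stats::cophenetic(tree)

  n <- length(tips)
  group <- character(n); status <- character(n)
  support <- rep(NA_real_, n); adist <- rep(NA_real_, n)
  names(group) <- names(status) <- names(support) <- names(adist) <- tips

  for (t in tips) {
    if (is_out[match(t, tips)]) { status[t] <- "outgroup"; next }
    if (t %in% anchors) {
      group[t] <- anchor_name[[t]]
      status[t] <- "anchored"
      next
    }
    holds <- vapply(clades, function(cl) t %in% cl && any(anchors %in% cl),
                    TRUE)
    if (!any(holds)) { status[t] <- "like"; next }     # grouped below
    k <- which(holds)[order(csize[holds])][1L]
    ca <- intersect(clades[[k]], anchors)
    nms <- sort(unique(anchor_name[ca]))
    dts <- D[t, ca]
    if (length(nms) == 1L) {
      group[t] <- nms
      status[t] <- "anchored"
    } else {
      near <- ca[order(dts, anchor_name[ca])][1L]
      group[t] <- anchor_name[[near]]
      status[t] <- "group_like"
    }
    support[t] <- csupport[k]
    adist[t] <- min(dts)
  }

  # like leaves: group by maximal supported clade made only of like leaves
  likes <- tips[status == "like"]
  if (length(likes)) {
    assigned <- character(0)
    group_no <- 0L
    for (t in tips[tips %in% likes]) {      # tip order => numbering order
      if (t %in% assigned) next
      cand <- clades[vapply(clades, function(cl)
        t %in% cl && all(cl %in% likes), TRUE)]
      members <- if (length(cand)) cand[[order(-vapply(cand, length, 0L))[1L]]]
                 else t
      group_no <- group_no + 1L
      gname <- paste0(config$like_prefix, " ", group_no)
      group[members] <- gname
      assigned <- c(assigned, members)
    }
  }

  asn <- data.frame(id = tips, species = sp, group = group, status = status,
                    support = support, anchor_dist = adist,
                    row.names = NULL)
  asn <- asn[asn$status != "outgroup", , drop = FALSE]
  gsum <- aggregate(cbind(n_members = rep(1L, nrow(asn))) ~ group + status,
                    data = asn, FUN = sum)
  structure(list(assignment = asn, groups = gsum,
                 reference_species = ref, config = config),
            class = "deg_groups")
}

#' @export
print.deg_groups <- function(x, ...) {
  cat("Ortholog groups (reference species:", x$reference_species, ")\n")
  cat(" ", nrow(x$assignment), "assigned members in",
      length(unique(x$assignment$group)), "groups;",
      sum(x$assignment$status == "like"), "like,",
      sum(x$assignment$status == "group_like"), "group-like\n")
  invisible(x)
}

#' Propose standardized names
#'
#' Builds species-prefixed names from the group assignment: a single member
#' of a group within a species is `<prefix><group>` (e.g. `PpDeg5`);
#' multiple same-species members get `.1`..`.m` suffixes ordered by
#' ascending patristic distance to the nearest anchor (lexicographic id
#' tie-break); group-like members append the configured suffix; reference
#' species keep their established names unchanged.
#'
#' @param groups a `deg_groups` from [assign_ortholog_groups()].
#' @param catalog the catalog (for species prefixes).
#' @param config a [nomenclature_config()].
#' @return named character vector, record id -> proposed name.
#' @export
propose_names <- function(groups, catalog, config = groups$config) {
  asn <- groups$assignment
  ref <- groups$reference_species
  nm <- character(nrow(asn))
  names(nm) <- asn$id
  for (g in unique(asn$group)) {
    for (s in unique(asn$species[asn$group == g])) {
      cell <- asn[asn$group == g & asn$species == s, , drop = FALSE]
      base <- if (cell$status[1L] == "group_like")
        paste0(g, "-", config$grouplike_suffix) else g
      if (s == ref) {
        nm[cell$id] <- paste0(s, cell$group)
      } else if (nrow(cell) == 1L) {
        nm[cell$id] <- paste0(s, base)
      } else {
        ord <- order(cell$anchor_dist, cell$id)
        nm[cell$id[ord]] <- paste0(s, base, ".", seq_len(nrow(cell)))
      }
    }
  }
  if (anyDuplicated(nm))
    stop("name collision: ", nm[duplicated(nm)][1L])
  nm
}

#' Check domain-arrangement concordance within groups
#'
#' Orthologs are expected to share the domain arrangement of their nearest
#' reference ortholog; per group this reports the majority architecture and
#' any discordant members.  It never fails the pipeline, only reports.
#'
#' @param groups a `deg_groups`.
#' @param catalog catalog carrying declared architectures.
#' @return data frame: `group`, `majority_architecture`, `n_members`,
#'   `discordant` (comma-separated ids), `unassessed` (ids lacking an
#'   architecture).
#' @export
architecture_concordance <- function(groups, catalog) {
  asn <- groups$assignment
  rec <- catalog$records
  arch <- rec$architecture[match(asn$id, rec$id)]
  out <- lapply(unique(asn$group), function(g) {
    sel <- asn$group == g
    a <- arch[sel]; ids <- asn$id[sel]
    known <- nzchar(a) & !is.na(a)
    if (!any(known))
      return(data.frame(group = g, majority_architecture = "",
                        n_members = sum(sel), discordant = "",
                        unassessed = paste(ids, collapse = ",")))
    tab <- sort(table(a[known]), decreasing = TRUE)
    maj <- names(tab)[order(-tab, names(tab))][1L]
    data.frame(group = g, majority_architecture = maj,
               n_members = sum(sel),
               discordant = paste(ids[known & a != maj], collapse = ","),
               unassessed = paste(ids[!known], collapse = ","))
  })
  do.call(rbind, out)
}

#' Report clade labels for groups
#'
#' Roman clade labels are reporting annotations attached by matching group
#' names to configured label sets; they carry no inferred semantics.
#'
#' @param groups a `deg_groups`.
#' @param labels named list, label -> character vector of group base names.
#' @export
label_clades <- function(groups,
                         labels = list(
                           "I A" = c("Deg1", "Deg5", "Deg8"),
                           "I B" = "Deg14",
                           "II" = c("Deg2", "Deg3", "Deg4", "Deg9", "Deg10",
                                    "Deg11", "Deg12", "Deg13"),
                           "III" = "Deg15",
                           "IV" = "Deg7")) {
  g <- unique(groups$assignment$group)
  lab <- vapply(g, function(x) {
    hit <- names(labels)[vapply(labels, function(v) x %in% v, TRUE)]
    if (length(hit)) hit[1L] else ""
  }, "")
  data.frame(group = g, clade = lab, row.names = NULL)
}
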