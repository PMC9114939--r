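# Vocal clan delineation: per-(group, day) usage repertoires, Bhattacharyya
# similarity, average-linkage clustering, identity-coda detection, the
# dendrogram cut search, and the robustness parameter sweep.

#' Build usage repertoires from typed codas
#'
#' All codas recorded from one group on one day are pooled into a usage
#' repertoire. Unclassified (contamination) codas count toward the
#' repertoire-size filter but never toward usage proportions. Repertoires
#' with fewer than `min_codas` codas are dropped (and counted). Days on which
#' several units were recorded together should arrive under a combined
#' `group_id` and so form a single repertoire.
#'
#' @param assignments data.frame of type assignments (`coda_id`, `type_id`)
#'   from [classify_codas()].
#' @param codas coda data.frame (`coda_id`, `group_id`, `date`).
#' @param min_codas minimum repertoire size (default 25).
#' @return object of class `usage_repertoires`: list with `counts` and
#'   `proportions` matrices (repertoires x types), `unclassified` counts,
#'   `repertoire_id`, `group_id`, `date` and a `dropped` bookkeeping
#'   data.frame.
#' @export
build_repertoires <- function(assignments, codas, min_codas = 25L) {
  df <- merge(codas[, c("coda_id", "group_id", "date")],
              assignments[, c("coda_id", "type_id")], by = "coda_id")
  df$repertoire_id <- paste(df$group_id, as.character(df$date), sep = "@")
  total <- table(df$repertoire_id)
  flt <- filter_repertoire_size(total, min_codas)
  keep <- df$repertoire_id %in% flt$kept_ids
  dropped <- data.frame(repertoire_id = flt$dropped_ids,
                        n_codas = as.integer(total[flt$dropped_ids]))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("no repertoire meets the size filter", call. = FALSE)
  classified <- df[df$type_id != "unclassified", , drop = FALSE]
  type_ids <- sort(unique(classified$type_id))
  rep_ids <- sort(unique(df$repertoire_id))
  counts <- table(factor(classified$repertoire_id, levels = rep_ids),
                  factor(classified$type_id, levels = type_ids))
  counts <- matrix(as.integer(counts), nrow = length(rep_ids),
                   dimnames = list(rep_ids, type_ids))
  uncl <- table(factor(df$repertoire_id[df$type_id == "unclassified"],
                       levels = rep_ids))
  props <- counts / pmax(rowSums(counts), 1L)
  meta <- unique(df[, c("repertoire_id", "group_id", "date")])
  meta <- meta[match(rep_ids, meta$repertoire_id), ]
  structure(list(counts = counts, proportions = props,
                 unclassified = as.integer(uncl),
                 repertoire_id = rep_ids, group_id = meta$group_id,
                 date = meta$date, dropped = dropped),
            class = "usage_repertoires")
}

#' @export
print.usage_repertoires <- function(x, ...) {
  cat(sprintf("Usage repertoires: %d repertoires x %d types (%d codas classified, %d unclassified, %d dropped in %d small repertoires)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              sum(x$unclassified), sum(x$dropped$n_codas), nrow(x$dropped)))
  invisible(x)
}

#' Acoustic similarity between usage repertoires
#'
#' Bhattacharyya coefficient between two type-usage distributions,
#' `sum_t sqrt(p_a(t) p_b(t))`, in [0, 1]; equal to 1 iff the distributions
#' are identical and 0 iff their supports are disjoint. The
#' `identity`-weighted mode restricts both distributions to the candidate
#' identity types and renormalises before comparing.
#'
#' @param a,b numeric usage vectors over a shared type space.
#' @param mode `"bhattacharyya"` (full usage) or `"identity"`.
#' @param identity_types type ids (or indices) defining the restricted space
#'   for the identity mode.
#' @return similarity in [0, 1].
#' @export
repertoire_similarity <- function(a, b, mode = c("bhattacharyya", "identity"),
                                  identity_types = NULL) {
  mode <- match.arg(mode)
  if (mode == "identity") {
    if (is.null(identity_types)) stop("identity mode needs identity_types", call. = FALSE)
    a <- a[identity_types]; b <- b[identity_types]
  }
  if (sum(a) <= 0 || sum(b) <= 0) {
    stop("zero-support repertoire in similarity computation", call. = FALSE)
  }
  sum(sqrt((a / sum(a)) * (b / sum(b))))
}

# similarity matrix over all repertoires (rows of a proportions matrix)
similarity_matrix <- function(P, mode = "bhattacharyya", identity_types = NULL) {
  if (mode == "identity") {
    P <- P[, identity_types, drop = FALSE]
    z <- rowSums(P)
    if (any(z <= 0)) {
      stop("zero-support repertoire under identity-type restriction", call. = FALSE)
    }
    P <- P / z
  }
  S <- sqrt(P) %*% t(sqrt(P))
  S[S > 1] <- 1
  diag(S) <- 1
  S
}

#' Average-linkage clustering of a similarity matrix
#'
#' Agglomerative average-linkage tree on distance `1 - similarity`. Rows are
#' pre-ordered lexicographically by label so that merge tie-breaking is
#' deterministic regardless of input order.
#'
#' @param S symmetric similarity matrix with unit diagonal, dimnames = labels.
#' @return an `hclust` tree.
#' @export
average_linkage <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (max(abs(S - t(S))) > 1e-8 || any(abs(diag(S) - 1) > 1e-8)) {
    stop("similarity matrix must be symmetric with unit diagonal", call. = FALSE)
  }
  labs <- rownames(S) %||% sprintf("r%03d", seq_len(nrow(S)))
  ord <- order(labs)
  D <- 1 - S[ord, ord]
  stats::hclust(stats::as.dist(D), method = "average")
}

#' Detect identity coda types for a partition of repertoires
#'
#' A type t is an identity coda of clan c when it is used consistently inside
#' c and rarely outside: the fraction of c's repertoires using t at
#' proportion >= `u_min` must reach `prevalence_min`, and the mean usage of t
#' outside c must not exceed `out_max`.
#'
#' @param reps a `usage_repertoires` object (or a proportions matrix).
#' @param partition clan labels, one per repertoire (any label type).
#' @param u_min usage proportion at which a repertoire counts as "using" t.
#' @param prevalence_min minimum within-clan prevalence of use.
#' @param out_max maximum mean usage outside the clan.
#' @return data.frame with columns `type_id`, `clan_id`, `inside_usage`,
#'   `outside_usage`, `inside_prevalence`.
#' @export
detect_identity_types <- function(reps, partition, u_min = 0.05,
                                  prevalence_min = 0.5, out_max = 0.05) {
  P <- if (inherits(reps, "usage_repertoires")) reps$proportions else as.matrix(reps)
  stopifnot(length(partition) == nrow(P))
  out <- list()
  for (cl in unique(partition)) {
    inside <- P[partition == cl, , drop = FALSE]
    outside <- P[partition != cl, , drop = FALSE]
    prev <- colMeans(inside >= u_min)
    in_mean <- colMeans(inside)
    out_mean <- if (nrow(outside) > 0L) colMeans(outside) else rep(0, ncol(P))
    hit <- which(prev >= prevalence_min & out_mean <= out_max)
    if (length(hit) > 0L) {
      out[[length(out) + 1L]] <- data.frame(
        type_id = colnames(P)[hit], clan_id = cl,
        inside_usage = unname(in_mean[hit]),
        outside_usage = unname(out_mean[hit]),
        inside_prevalence = unname(prev[hit]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(type_id = character(0), clan_id = character(0),
                      inside_usage = numeric(0), outside_usage = numeric(0),
                      inside_prevalence = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# vectorised validity check of one dendrogram cut: every cluster must own at
# least one exclusive identity type (a type qualifying for two sister
# clusters distinguishes neither, so shared claims are discarded)
valid_cut <- function(P, part, u_min, prevalence_min, out_max) {
  k <- max(part)
  sizes <- tabulate(part, k)
  n <- nrow(P)
  csum <- rowsum(P, part)                      # k x T usage sums
  prev <- rowsum((P >= u_min) + 0, part) / sizes
  out_mean <- (rep(colSums(P), each = k) - csum) / pmax(n - sizes, 1L)
  id <- prev >= prevalence_min & out_mean <= out_max
  if (k == 1L) return(any(id))
  excl <- colSums(id) == 1L
  all(rowSums(id[, excl, drop = FALSE]) > 0)
}

# exclusive identity types of a partition (data.frame form)
exclusive_identity_types <- function(P, part, u_min, prevalence_min, out_max) {
  idt <- detect_identity_types(P, part, u_min, prevalence_min, out_max)
  shared <- names(which(table(idt$type_id) > 1L))
  idt <- idt[!idt$type_id %in% shared, , drop = FALSE]
  rownames(idt) <- NULL
  idt
}

# agreement (ARI) between a cut and its identity-weighted re-clustering;
# NA when the check cannot be carried out (e.g. zero identity-type support)
cut_stability <- function(P, part, u_min, prevalence_min, out_max) {
  idt <- exclusive_identity_types(P, part, u_min, prevalence_min, out_max)
  if (nrow(idt) == 0L) return(NA_real_)
  tryCatch({
    S2 <- similarity_matrix(P, mode = "identity",
                            identity_types = unique(idt$type_id))
    rownames(S2) <- colnames(S2) <- rownames(P)
    tree2 <- average_linkage(S2)
    part2 <- stats::cutree(tree2, k = max(part))
    mclust::adjustedRandIndex(part[rownames(P)], part2[rownames(P)])
  }, error = function(e) NA_real_)
}

#' Delineate vocal clans from usage repertoires
#'
#' Repertoires are clustered by average linkage on full-usage Bhattacharyya
#' similarity; every cut of the dendrogram (k = 1..n clusters) is scored by
#' whether each cluster owns at least one identity coda type claimed by no
#' other cluster, and the deepest such cut is accepted. Over-splitting
#' destroys identity types (the sister half of a split clan either pushes
#' outside usage over `out_max` or claims the same type, which then
#' distinguishes neither half), so the search is self-limiting. The accepted
#' partition is re-clustered on
#' identity-weighted similarity as a stability check (its agreement with the
#' full-usage partition is reported as an adjusted Rand index). When no
#' multi-cluster cut qualifies, a single clan is returned with a note.
#'
#' @param reps a `usage_repertoires` object.
#' @inheritParams detect_identity_types
#' @param k_max deepest cut to consider (default: number of repertoires).
#' @return object of class `clan_assignment`: `clans` (named vector
#'   repertoire_id -> clan id, clans numbered by decreasing size),
#'   `identity_types`, `tree` (hclust), `k`, `stability_ari`, `note`,
#'   `params`.
#' @export
delineate_clans <- function(reps, u_min = 0.05, prevalence_min = 0.5,
                            out_max = 0.05, k_max = NULL) {
  stopifnot(inherits(reps, "usage_repertoires"))
  P <- reps$proportions
  n <- nrow(P)
  if (n < 2L) stop("need at least two repertoires", call. = FALSE)
  S <- similarity_matrix(P)
  tree <- average_linkage(S)
  P <- P[tree$labels, , drop = FALSE]  # align with lexicographic tree order
  k_max <- min(k_max %||% n, n)
  cuts <- stats::cutree(tree, k = seq_len(k_max))
  if (!is.matrix(cuts)) cuts <- matrix(cuts, ncol = 1L, dimnames = list(tree$labels, NULL))
  valid <- vapply(seq_len(k_max), function(k)
    valid_cut(P, cuts[, k], u_min, prevalence_min, out_max), logical(1))
  # deepest valid cut that is reproduced exactly by identity-weighted
  # re-clustering; deepest valid cut (with a note) if none is stable
  best_k <- 1L
  stability <- NA_real_
  note <- ""
  deep <- rev(setdiff(which(valid), 1L))
  for (k in deep) {
    st <- cut_stability(P, cuts[, k], u_min, prevalence_min, out_max)
    if (!is.na(st) && st >= 1 - 1e-12) {
      best_k <- k
      stability <- st
      break
    }
  }
  if (best_k == 1L && length(deep) > 0L) {
    best_k <- deep[1L]
    stability <- cut_stability(P, cuts[, best_k], u_min, prevalence_min, out_max)
    note <- "no valid cut was stable under identity-weighted re-clustering; deepest valid cut returned"
  }
  if (best_k == 1L && length(deep) == 0L) {
    note <- "no multi-cluster cut gave every cluster an exclusive identity coda type; single clan returned"
  }
  part <- stats::setNames(cuts[, best_k], tree$labels)
  # stable clan ids by decreasing cluster size (ties by smallest member label)
  sizes <- table(part)
  first_lab <- vapply(split(names(part), part), min, character(1))
  ord <- order(-as.integer(sizes), first_lab)
  relabel <- stats::setNames(sprintf("C%d", seq_along(ord)), names(sizes)[ord])
  clans <- stats::setNames(unname(relabel[as.character(part)]), names(part))
  idt <- exclusive_identity_types(P, clans[rownames(P)], u_min, prevalence_min,
                                  out_max)
  structure(list(clans = clans, identity_types = idt, tree = tree, k = best_k,
                 stability_ari = stability, note = note,
                 params = list(u_min = u_min, prevalence_min = prevalence_min,
                               out_max = out_max)),
            class = "clan_assignment")
}

#' @export
print.clan_assignment <- function(x, ...) {
  cat(sprintf("Vocal clan assignment: %d repertoires in %d clan(s); %d identity coda type(s)\n",
              length(x$clans), x$k, nrow(x$identity_types)))
  print(table(x$clans))
  if (!is.na(x$stability_ari)) {
    cat(sprintf("identity-weighted re-clustering agreement (ARI): %.3f\n", x$stability_ari))
  }
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# canonical string form of a partition (labels by order of first appearance)
canonical_partition <- function(part, ids) {
  part <- part[ids]
  paste(match(part, unique(part)), collapse = ".")
}

#' Robustness sweep over clan-delineation parameters
#'
#' Re-runs [delineate_clans()] over a grid of identity-coda thresholds and
#' reports how stable the resulting partition is: the pairwise adjusted Rand
#' index between grid points and the fraction of grid points whose partition
#' equals the modal (most frequent) partition.
#'
#' @param reps a `usage_repertoires` object.
#' @param u_min,prevalence_min,out_max numeric vectors spanning the grid.
#' @return list with `table` (one row per grid point: parameters, number of
#'   clans, agreement with the modal partition), `ari` (grid x grid matrix),
#'   `agreement` (fraction agreeing with the modal partition) and
#'   `modal_n_clans`.
#' @export
sweep_parameters <- function(reps, u_min = c(0.03, 0.05, 0.10),
                             prevalence_min = c(0.4, 0.5, 0.6),
                             out_max = c(0.03, 0.05, 0.10)) {
  grid <- expand.grid(u_min = u_min, prevalence_min = prevalence_min,
                      out_max = out_max, KEEP.OUT.ATTRS = FALSE)
  ids <- sort(rownames(reps$proportions))
  parts <- vector("list", nrow(grid))
  n_clans <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ca <- delineate_clans(reps, u_min = grid$u_min[i],
                          prevalence_min = grid$prevalence_min[i],
                          out_max = grid$out_max[i])
    parts[[i]] <- ca$clans
    n_clans[i] <- ca$k
  }
  canon <- vapply(parts, canonical_partition, character(1), ids = ids)
  modal <- names(which.max(table(canon)))
  agree_modal <- canon == modal
  m <- length(parts)
  ari <- matrix(1, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      ari[i, j] <- ari[j, i] <-
        mclust::adjustedRandIndex(parts[[i]][ids], parts[[j]][ids])
    }
  }
  tab <- cbind(grid, n_clans = n_clans, agrees_with_modal = agree_modal)
  list(table = tab, ari = ari, agreement = mean(agree_modal),
       modal_n_clans = n_clans[match(modal, canon)])
}

#' Heat-map shading of usage proportions
#'
#' Bins a usage proportion into the four display shades used for repertoire
#' heat maps: `white` for exactly 0, `light` for (0, 0.05], `mid` for
#' (0.05, 0.10] and `dark` above 0.10.
#'
#' @param proportion numeric vector in [0, 1].
#' @return factor with levels `white`, `light`, `mid`, `dark`.
#' @export
heatmap_bins <- function(proportion) {
  if (any(!is.finite(proportion)) || any(proportion < 0) || any(proportion > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  out <- ifelse(proportion == 0, "white",
                ifelse(proportion <= 0.05, "light",
                       ifelse(proportion <= 0.10, "mid", "dark")))
  factor(out, levels = c("white", "light", "mid", "dark"))
}

#' Export clan-delineation results
#'
#' Writers for the long-format repertoire table
#' (`repertoire_id,type_id,count,proportion`), the clan table, the identity
#' type table, a shade-category heat-map matrix, and the dendrogram in Newick
#' form (branch lengths = merge heights).
#'
#' @param reps a `usage_repertoires` object.
#' @param path file path.
#' @name write_clan_outputs
#' @export
write_repertoires <- function(reps, path) {
  long <- data.frame(
    repertoire_id = rep(rownames(reps$counts), times = ncol(reps$counts)),
    type_id = rep(colnames(reps$counts), each = nrow(reps$counts)),
    count = as.integer(reps$counts),
    proportion = as.numeric(reps$proportions))
  long <- long[long$count > 0L, ]
  long <- long[order(long$repertoire_id, long$type_id), ]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clan_outputs
#' @param ca a `clan_assignment` object.
#' @export
write_clans <- function(ca, path) {
  df <- data.frame(repertoire_id = names(ca$clans), clan_id = unname(ca$clans))
  utils::write.csv(df[order(df$repertoire_id), ], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_clan_outputs
#' @export
write_identity_types <- function(ca, path) {
  utils::write.csv(ca$identity_types, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clan_outputs
#' @export
write_heatmap <- function(reps, ca, path) {
  idt <- unique(ca$identity_types$type_id)
  shades <- matrix(as.character(heatmap_bins(as.numeric(reps$proportions[, idt]))),
                   nrow = nrow(reps$proportions),
                   dimnames = list(rownames(reps$proportions), idt))
  utils::write.csv(as.data.frame(shades), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_clan_outputs
#' @param tree an `hclust` tree (e.g. `ca$tree`).
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
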