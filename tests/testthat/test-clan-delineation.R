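# Clan delineation: repertoire building, similarity, clustering, identity
# types, the cut search, the parameter sweep and heat-map binning.

# small shared fixture: typed codas from a reduced three-clan world
small_world <- local({
  g <- gen_codas(n_groups_per_clan = c(6, 5, 4), days_per_group = 3,
                 coda_day_mean = 80, seed = 31)
  cc <- classify_codas(g$codas, k_max = 5, seed = 4)
  reps <- build_repertoires(cc$assignments, g$codas)
  list(g = g, cc = cc, reps = reps)
})

test_that("repertoires normalise, respect the size filter, and count cells", {
  # 30 codas of one type on one day -> proportion 1
  assigns <- data.frame(coda_id = sprintf("c%d", 1:30), type_id = "5-1")
  codas <- data.frame(coda_id = sprintf("c%d", 1:30), group_id = "g1",
                      date = as.Date("2019-02-01"))
  r <- build_repertoires(assigns, codas)
  expect_equal(unname(r$proportions[1, "5-1"]), 1)
  # 24 codas on a day -> no repertoire
  expect_error(build_repertoires(assigns[1:24, ], codas[1:24, ]), "size filter")
  # generator bookkeeping: one repertoire per >= 25-coda (group, day) cell
  w <- small_world
  expect_equal(sort(rownames(w$reps$proportions)),
               sort(w$g$truth$cells$repertoire_id[!w$g$truth$cells$subthreshold]))
  expect_true(all(abs(rowSums(w$reps$proportions) - 1) < 1e-9))
})

test_that("Bhattacharyya similarity has its closed-form values and range", {
  expect_equal(repertoire_similarity(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(repertoire_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(repertoire_similarity(c(0.5, 0.5), c(1, 0)), sqrt(0.5))
  expect_error(repertoire_similarity(c(0, 0), c(1, 0)), "zero-support")
  set.seed(41)
  for (r in 1:25) {
    p <- runif(6); q <- runif(6)
    s <- repertoire_similarity(p, q)
    expect_gte(s, 0); expect_lte(s, 1 + 1e-12)
  }
  # equals 1 iff equal distributions
  p <- runif(6); p <- p / sum(p)
  q <- p; q[1] <- q[1] + 0.05; q <- q / sum(q)
  expect_lt(repertoire_similarity(p, q), 1)
})

test_that("average linkage matches a naive O(n^3) oracle", {
  # two identical items merge first
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 1
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- 0.2
  rownames(S) <- colnames(S) <- c("a", "b", "c")
  tr <- average_linkage(S)
  expect_equal(sort(tr$merge[1, ]), c(-2, -1))
  # random matrices vs naive agglomeration (cophenetic distances)
  set.seed(42)
  for (r in 1:5) {
    n <- 8
    D <- matrix(runif(n * n, 0.1, 1), n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    S <- 1 - D
    rownames(S) <- colnames(S) <- sprintf("r%02d", 1:n)
    tr <- average_linkage(S)
    C <- as.matrix(stats::cophenetic(tr))
    C <- C[rownames(S), rownames(S)]
    expect_equal(unname(C), unname(naive_avg_linkage_cophenetic(D)),
                 tolerance = 1e-10)
  }
  # perfect 3-block matrix: cutting between merges yields the blocks
  B <- matrix(0.1, 9, 9)
  for (b in 0:2) B[b * 3 + 1:3, b * 3 + 1:3] <- 0.9
  diag(B) <- 1
  rownames(B) <- colnames(B) <- sprintf("x%d", 1:9)
  tb <- average_linkage(B)
  expect_equal(as.integer(table(stats::cutree(tb, 3))), rep(3L, 3))
})

test_that("identity-type detection applies its thresholds", {
  P <- rbind(matrix(c(0.5, 0.3, 0.2), 5, 3, byrow = TRUE),
             matrix(c(0.0, 0.3, 0.7), 5, 3, byrow = TRUE))
  colnames(P) <- c("t1", "t2", "t3")
  part <- rep(c("A", "B"), each = 5)
  idt <- detect_identity_types(P, part, u_min = 0.05, prevalence_min = 0.5,
                               out_max = 0.05)
  # t1: used at 0.5 in every A repertoire, 0 elsewhere -> identity of A
  expect_true(any(idt$type_id == "t1" & idt$clan_id == "A"))
  # t2 used at 0.3 everywhere -> identity of no clan
  expect_false("t2" %in% idt$type_id)
})

test_that("three planted clans are recovered with ARI 1 and exact identity types", {
  w <- small_world
  ca <- delineate_clans(w$reps)
  truth <- w$g$truth$cells
  tr <- truth$clan_id[match(names(ca$clans), truth$repertoire_id)]
  expect_equal(ca$k, 3L)
  expect_equal(mclust::adjustedRandIndex(ca$clans, tr), 1)
  # identity types recovered exactly (as clan-label pairs), no false positives
  lab <- w$cc$types$label[match(ca$identity_types$type_id, w$cc$types$type_id)]
  map <- tapply(ca$clans, tr, function(x) names(which.max(table(x))))
  planted <- sort(paste(map[w$g$truth$identity_types$clan_id],
                        w$g$truth$identity_types$label))
  expect_equal(sort(paste(ca$identity_types$clan_id, lab)), planted)
  # group-level clan sizes match the generator design
  grp <- tapply(ca$clans, w$reps$group_id[match(names(ca$clans), w$reps$repertoire_id)],
                function(x) names(which.max(table(x))))
  expect_equal(as.integer(sort(table(grp), decreasing = TRUE)), c(6L, 5L, 4L))
  # self-consistency: every identity type passes its thresholds when re-checked
  re <- detect_identity_types(w$reps$proportions[names(ca$clans), ], ca$clans,
                              0.05, 0.5, 0.05)
  expect_true(all(paste(ca$identity_types$type_id, ca$identity_types$clan_id) %in%
                    paste(re$type_id, re$clan_id)))
})

test_that("duplicated repertoires give a single clan with a note", {
  P <- matrix(rep(c(0.6, 0.3, 0.1), 10), ncol = 3, byrow = TRUE)
  colnames(P) <- c("t1", "t2", "t3")
  rownames(P) <- sprintf("r%02d", 1:10)
  reps <- structure(list(proportions = P, counts = P * 100,
                         repertoire_id = rownames(P)),
                    class = "usage_repertoires")
  ca <- delineate_clans(reps)
  expect_equal(ca$k, 1L)
  expect_match(ca$note, "single clan")
})

test_that("clan assignment is invariant to repertoire relabelling and order", {
  w <- small_world
  ca1 <- delineate_clans(w$reps)
  reps2 <- w$reps
  perm <- sample(nrow(reps2$proportions))
  reps2$proportions <- reps2$proportions[perm, ]
  reps2$counts <- reps2$counts[perm, ]
  reps2$repertoire_id <- reps2$repertoire_id[perm]
  reps2$group_id <- reps2$group_id[perm]
  ca2 <- delineate_clans(reps2)
  common <- names(ca1$clans)
  expect_equal(mclust::adjustedRandIndex(ca1$clans[common], ca2$clans[common]), 1)
})

test_that("parameter sweep is stable on clan data and collapses on a null world", {
  w <- small_world
  sw <- sweep_parameters(w$reps)
  expect_gte(sw$agreement, 0.9)
  expect_equal(sw$modal_n_clans, 3L)
  # degenerate one-point grid
  sw1 <- sweep_parameters(w$reps, u_min = 0.05, prevalence_min = 0.5,
                          out_max = 0.05)
  expect_equal(sw1$agreement, 1)
  # label-free null: all clans share the pooled usage mix
  gn <- gen_codas(null_clan_specs(), n_groups_per_clan = c(6, 5, 4),
                  days_per_group = 3, coda_day_mean = 80, seed = 32)
  ccn <- classify_codas(gn$codas, k_max = 5, seed = 5)
  repsn <- build_repertoires(ccn$assignments, gn$codas)
  swn <- sweep_parameters(repsn)
  expect_true(swn$modal_n_clans == 1L || swn$agreement < 0.5)
})

test_that("heat-map bins follow the published shade boundaries", {
  expect_equal(as.character(heatmap_bins(c(0, 0.05, 0.07, 0.54))),
               c("white", "light", "mid", "dark"))
  expect_equal(as.character(heatmap_bins(0.101)), "dark")
  expect_error(heatmap_bins(1.2), "0, 1")
  expect_error(heatmap_bins(-0.1), "0, 1")
})

test_that("clan outputs round-trip to csv and newick", {
  w <- small_world
  ca <- delineate_clans(w$reps)
  td <- withr::local_tempdir()
  write_repertoires(w$reps, file.path(td, "repertoires.csv"))
  write_clans(ca, file.path(td, "clans.csv"))
  write_identity_types(ca, file.path(td, "identity_types.csv"))
  write_heatmap(w$reps, ca, file.path(td, "heatmap.csv"))
  write_dendrogram_newick(ca$tree, file.path(td, "dendrogram.nwk"))
  cl <- utils::read.csv(file.path(td, "clans.csv"))
  expect_equal(nrow(cl), length(ca$clans))
  tre <- ape::read.tree(file.path(td, "dendrogram.nwk"))
  expect_equal(sort(tre$tip.label), sort(names(ca$clans)))
})
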