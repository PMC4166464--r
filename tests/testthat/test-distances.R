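test_that("coverage filter drops exactly the under-resolved specimens", {
  aln <- dna_alignment(c(full = "ACGTACGTAC", low = "AC--??????",
                         mid = "ACGTA?????"), "t")
  out <- coverage_filter(aln, 0.5)
  expect_equal(attr(out, "excluded_ids"), "low")   # 20% resolved
  expect_setequal(specimen_ids(out), c("full", "mid"))  # 50% passes (>=)

  ok <- coverage_filter(dna_alignment(c(a = "ACGT", b = "ACGA"), "t"), 0.5)
  expect_length(attr(ok, "excluded_ids"), 0)

  expect_error(coverage_filter(dna_alignment(c(a = "????", b = "--??"), "t")),
               "all specimens")

  set.seed(20)
  m <- matrix(sample(c("A", "C", "G", "T"), 10 * 40, replace = TRUE), 10, 40)
  rownames(m) <- sprintf("r%02d", 1:10)
  low_rows <- c(2, 5, 9)
  for (r in low_rows) m[r, 1:25] <- "?"   # 15/40 resolved < 0.5
  filt <- coverage_filter(dna_alignment(m, "t"), 0.5)
  expect_setequal(attr(filt, "excluded_ids"), rownames(m)[low_rows])
})

test_that("trimming shifts coordinates consistently and round-trips", {
  aln <- rand_alignment(4, 10, p_gap = 0)
  full <- trim_alignment(aln, 1, 10)
  expect_equal(unclass(full), unclass(aln), ignore_attr = TRUE)
  expect_equal(attr(full, "coordinate_offset"), 0L)
  tr <- trim_alignment(aln, 3, 7)
  expect_equal(n_columns(tr), 5L)
  expect_equal(unclass(tr)[, 1], unclass(aln)[, 3])
  # a position found post-trim maps back through the stored offset
  pos_post <- 2L
  expect_equal(pos_post + attr(tr, "coordinate_offset"), 4L)
  expect_equal(unclass(tr)[, pos_post], unclass(aln)[, 4])
  expect_error(trim_alignment(aln, 5, 3), "interval")
  expect_error(trim_alignment(aln, 0, 3), "interval")
})

test_that("p-distance handles the worked examples", {
  expect_equal(pairwise_p_distance(
    dna_alignment(c(a = "ACGT", b = "ACGT"), "t"))$distance["a", "b"], 0)
  expect_equal(pairwise_p_distance(
    dna_alignment(c(a = "AAAA", b = "TTTT"), "t"))$distance["a", "b"], 1)
  dm <- pairwise_p_distance(dna_alignment(c(a = "AC-GT", b = "ACCGA"), "t"))
  expect_equal(dm$distance["a", "b"], 0.25)        # gap column dropped
  expect_equal(dm$comparable_sites["a", "b"], 4L)
  # zero comparable sites is undefined, not zero
  dm2 <- pairwise_p_distance(dna_alignment(c(a = "AC??", b = "??GT"), "t"))
  expect_true(is.na(dm2$distance["a", "b"]))
  # ambiguity overlap counts as a match
  dm3 <- pairwise_p_distance(dna_alignment(c(a = "RG", b = "AC"), "t"))
  expect_equal(dm3$distance["a", "b"], 0.5)
})

test_that("p-distance agrees with the brute-force oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    aln <- rand_alignment(sample(3:8, 1), sample(10:50, 1))
    got <- pairwise_p_distance(aln)
    want <- oracle_p_distance(aln)
    expect_equal(got$distance, want$distance)
    expect_equal(got$comparable_sites, want$comparable_sites)
  }
})

test_that("p-distance is invariant under specimen and column permutation", {
  set.seed(32)
  aln <- rand_alignment(6, 30)
  dm <- pairwise_p_distance(aln)
  perm <- sample(specimen_ids(aln))
  dm_p <- pairwise_p_distance(
    dna_alignment(unclass(aln)[perm, ], locus_name = "t"))
  expect_equal(dm_p$distance[specimen_ids(aln), specimen_ids(aln)],
               dm$distance)
  cols <- sample(n_columns(aln))
  dm_c <- pairwise_p_distance(
    dna_alignment(unclass(aln)[, cols], locus_name = "t"))
  expect_equal(dm_c$distance, dm$distance)
})

test_that("group summary matches direct means and flags singletons", {
  aln <- dna_alignment(c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA",
                         b1 = "CCCCCCCCAA", b2 = "CCCCCCCCAA"), "t")
  part <- tibble::tibble(specimen_id = c("a1", "a2", "b1", "b2"),
                         group = c("A", "A", "B", "B"))
  s <- group_summary(pairwise_p_distance(aln), part)
  expect_equal(s$mean_intra, c(0, 0))
  expect_equal(s$min_mean_inter, c(0.8, 0.8))

  part2 <- tibble::tibble(specimen_id = c("a1", "a2", "b1", "b2"),
                          group = c("A", "A", "B", "C"))
  s2 <- group_summary(pairwise_p_distance(aln), part2)
  expect_true(is.na(s2$mean_intra[s2$group == "C"]))

  # brute-force recomputation on a random instance
  set.seed(41)
  cl <- rand_clustered_alignment(3, 5, 60)
  dm <- pairwise_p_distance(cl$aln)
  s3 <- group_summary(dm, cl$truth)
  grp <- setNames(cl$truth$group, cl$truth$specimen_id)
  for (g in s3$group) {
    ids <- names(grp)[grp == g]
    vals <- dm$distance[ids, ids][upper.tri(dm$distance[ids, ids])]
    expect_equal(s3$mean_intra[s3$group == g], mean(vals))
    inter <- sapply(setdiff(s3$group, g), function(h) {
      mean(dm$distance[ids, names(grp)[grp == h]])
    })
    expect_equal(s3$min_mean_inter[s3$group == g], min(inter))
    expect_equal(s3$nearest_group[s3$group == g], names(which.min(inter)))
  }
})

test_that("relative threshold test applies the inclusive 2x rule", {
  mk <- function(intra, inter) {
    s <- tibble::tibble(group = "g", n = ifelse(is.na(intra), 1L, 5L),
                        mean_intra = intra, nearest_group = "h",
                        min_mean_inter = inter)
    relative_threshold_test(s)
  }
  r <- mk(0.001, 0.048)           # published-style 4.8%/0.1%
  expect_equal(r$ratio, 48)
  expect_true(r$passes)
  r2 <- mk(0.002, 0.004)          # exactly 2x: inclusive boundary
  expect_equal(r2$ratio, 2)
  expect_true(r2$passes)
  r3 <- mk(0.003, 0.005)
  expect_false(r3$passes)
  expect_equal(r3$ratio, 5 / 3, tolerance = 1e-12)
  r4 <- mk(NA_real_, 0.01)        # singleton: passes with flag
  expect_true(r4$passes)
  expect_true(r4$intra_undefined)
  expect_equal(r4$ratio, Inf)
})

test_that("distance discovery recovers planted clusters and degenerate cases", {
  set.seed(51)
  # two clusters of identical sequences at clear separation
  aln <- dna_alignment(c(a1 = "AAAAAAAAAAAAAAAAAAAA", a2 = "AAAAAAAAAAAAAAAAAAAA",
                         b1 = "AAAAAAAAAAAAAAAATTTT", b2 = "AAAAAAAAAAAAAAAATTTT"),
                       "t")
  p <- discover_distance_groups(pairwise_p_distance(aln))
  expect_equal(length(unique(p$group)), 2L)
  expect_equal(p$group[p$specimen_id == "a1"], p$group[p$specimen_id == "a2"])

  # all identical -> one group
  same <- dna_alignment(c(x = "ACGT", y = "ACGT", z = "ACGT"), "t")
  p1 <- discover_distance_groups(pairwise_p_distance(same))
  expect_equal(length(unique(p1$group)), 1L)

  # planted multi-cluster instances with within-group noise
  for (rep in 1:5) {
    k <- sample(3:5, 1)
    cl <- rand_clustered_alignment(k, sample(3:6, 1), 80)
    p2 <- discover_distance_groups(pairwise_p_distance(cl$aln))
    expect_equal(compare_partitions(p2, cl$truth), 1.0)
  }
})

test_that("discovery is stable under specimen relabeling and reordering", {
  set.seed(61)
  cl <- rand_clustered_alignment(4, 4, 80)
  p <- discover_distance_groups(pairwise_p_distance(cl$aln))
  perm <- sample(nrow(cl$aln))
  m2 <- unclass(cl$aln)[perm, ]
  rownames(m2) <- paste0("zz_", rownames(m2))
  p2 <- discover_distance_groups(pairwise_p_distance(dna_alignment(m2, "t")))
  p2$specimen_id <- sub("^zz_", "", p2$specimen_id)
  expect_equal(compare_partitions(p, p2), 1.0)
})

test_that("merging any two discovered groups breaks the 2x criterion on an equidistant instance", {
  # constructed geometry: all between-group distances equal, so a merged
  # group's intra mean is ~half the between distance and its ratio falls
  # below 2
  set.seed(71)
  L <- 360
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  blocks <- split(1:300, rep(1:6, each = 50))
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  mk_group <- function(g) {
    proto <- base
    proto[blocks[[g]]] <- rot[proto[blocks[[g]]]]  # unique 50-site block
    sapply(1:4, function(i) {
      s <- proto
      hit <- sample(setdiff(1:L, unlist(blocks)), 2)  # tiny within noise
      s[hit] <- rot[s[hit]]
      paste(s, collapse = "")
    })
  }
  seqs <- unlist(lapply(1:4, mk_group))
  names(seqs) <- sprintf("g%d_%d", rep(1:4, each = 4), rep(1:4, 4))
  dm <- pairwise_p_distance(dna_alignment(seqs, "t"))
  part <- discover_distance_groups(dm)
  expect_equal(length(unique(part$group)), 4L)
  groups <- unique(part$group)
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (i >= j) next
    merged <- part
    merged$group[merged$group == groups[j]] <- groups[i]
    tt <- relative_threshold_test(group_summary(dm, merged))
    expect_false(tt$passes[tt$group == groups[i]])
  }
})
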