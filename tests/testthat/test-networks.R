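test_that("haplotype collapsing merges identical and missing-compatible sequences", {
  aln <- dna_alignment(setNames(rep("ACGTACGT", 5), paste0("s", 1:5)), "t")
  h <- collapse_haplotypes(aln)
  expect_equal(nrow(h), 1L)
  expect_equal(h$multiplicity, 5L)

  two <- collapse_haplotypes(
    dna_alignment(c(a = "ACGTACGT", b = "ACGTACGA"), "t"))
  expect_equal(nrow(two), 2L)

  # missing matches any state by default, not under strict mode
  part <- dna_alignment(c(a = "ACGTACGT", b = "ACGTAC??"), "t")
  expect_equal(nrow(collapse_haplotypes(part)), 1L)
  expect_equal(nrow(collapse_haplotypes(part, missing_matches = FALSE)), 2L)
})

test_that("haplotype count equals the brute-force duplicate scan", {
  set.seed(81)
  for (rep in 1:20) {
    aln <- rand_alignment(20, sample(8:30, 1), p_gap = 0.04, p_missing = 0.08)
    expect_equal(nrow(collapse_haplotypes(aln)), oracle_haplotype_count(aln))
  }
})

test_that("step distance treats gaps as a fifth state and skips missing", {
  expect_equal(step_distance("ACGT", "ACGT"), 0L)
  expect_equal(step_distance("AC-T", "ACTT"), 1L)   # base vs gap = 1 step
  expect_equal(step_distance("AC-T", "AC-T"), 0L)   # gap vs gap = same state
  expect_equal(step_distance("AC?T", "ACGT"), 0L)   # missing: no step
  expect_equal(step_distance("RCGT", "ACGT"), 0L)   # overlapping ambiguity
  set.seed(91)
  for (rep in 1:30) {
    aln <- rand_alignment(2, sample(5:40, 1))
    m <- unclass(aln)
    expect_equal(step_distance(m[1, ], m[2, ]),
                 oracle_step_distance(m[1, ], m[2, ]))
  }
})

test_that("connection limit is monotone and matches the independent evaluation", {
  # a probability limit above P_1 isolates every haplotype
  cl0 <- connection_limit(10, 0.999)
  expect_equal(cl0$j_max, 0L)
  # relaxing the limit never lowers j_max; P_j non-increasing
  for (L in c(300, 328, 1502, 2009)) {
    c98 <- connection_limit(L, 0.98)
    c90 <- connection_limit(L, 0.90)
    expect_gte(c90$j_max, c98$j_max)
    expect_true(all(diff(c98$p_j) <= 1e-12))
  }
  # independent numerical recomputation (root-finding path)
  for (L in c(100, 300, 1000)) {
    for (pl in c(0.90, 0.95, 0.98)) {
      expect_equal(connection_limit(L, pl)$j_max, oracle_j_max(L, pl),
                   info = paste(L, pl))
    }
  }
})

test_that("network components match a BFS oracle and handle extremes", {
  same <- collapse_haplotypes(
    dna_alignment(setNames(rep("ACGTACGTACGTACGTACGT", 4), paste0("s", 1:4)), "t"))
  expect_equal(n_networks(build_networks(same, fixed_steps = 1)), 1L)

  # two haplotypes at j_max + 1 steps fall into two networks
  pair <- collapse_haplotypes(
    dna_alignment(c(a = "AAAAAAAAAA", b = "TTTAAAAAAA"), "t"))
  expect_equal(n_networks(build_networks(pair, fixed_steps = 2)), 2L)
  expect_equal(n_networks(build_networks(pair, fixed_steps = 3)), 1L)

  # planted chain: consecutive haplotypes 2 steps apart; threshold at 2
  # connects the chain, 1 splits it into singletons
  L <- 40
  proto <- strsplit(paste(rep("A", L), collapse = ""), "")[[1]]
  seqs <- sapply(0:11, function(k) {
    s <- proto
    if (k > 0) s[seq_len(2 * k)] <- "T"
    paste(s, collapse = "")
  })
  names(seqs) <- sprintf("h%02d", 0:11)
  chain <- collapse_haplotypes(dna_alignment(seqs, "t"))
  nets2 <- build_networks(chain, fixed_steps = 2)
  expect_equal(n_networks(nets2), 1L)
  nets1 <- build_networks(chain, fixed_steps = 1)
  expect_equal(n_networks(nets1), 12L)

  set.seed(101)
  for (rep in 1:15) {
    aln <- rand_alignment(sample(8:25, 1), sample(10:40, 1), p_missing = 0)
    haps <- collapse_haplotypes(aln)
    jm <- sample(0:6, 1)
    nets <- build_networks(haps, fixed_steps = jm)
    want <- oracle_components(attr(nets, "steps"), jm)
    got <- setNames(as.integer(factor(nets$network)), nets$haplotype)
    expect_true(same_partition(got[names(want)], unname(want)))
  }
})

test_that("components are invariant to input order and j_max >= max distance gives one network", {
  set.seed(111)
  aln <- rand_alignment(12, 30, p_missing = 0)
  haps <- collapse_haplotypes(aln)
  nets <- build_networks(haps, fixed_steps = 3)
  perm <- sample(nrow(aln))
  aln2 <- dna_alignment(unclass(aln)[perm, ], "t")
  nets2 <- build_networks(collapse_haplotypes(aln2), fixed_steps = 3)
  t1 <- tidy(nets); t2 <- tidy(nets2)
  m <- merge(t1, t2, by = "specimen_id")
  expect_true(same_partition(m$network.x, m$network.y))

  big <- max(attr(nets, "steps"))
  expect_equal(n_networks(build_networks(haps, fixed_steps = big)), 1L)
})

test_that("network separation reports exclusive, split and shared cases", {
  # groups A (identical pair), B (identical pair) far apart: exclusive nets
  L <- 30
  a <- paste(rep("A", L), collapse = "")
  b <- paste(c(rep("A", L - 10), rep("T", 10)), collapse = "")
  aln <- dna_alignment(c(a1 = a, a2 = a, b1 = b, b2 = b), "t")
  part <- tibble::tibble(specimen_id = c("a1", "a2", "b1", "b2"),
                         group = c("A", "A", "B", "B"))
  nets <- build_networks(collapse_haplotypes(aln), fixed_steps = 3)
  sA <- network_separation(nets, part, "A")
  expect_true(sA$is_separate)
  expect_equal(sA$n_networks_spanned, 1L)
  expect_true(is.na(sA$min_steps_to_nonmember))

  # group split over two exclusive networks: still separate, spans 2
  c1 <- paste(c(rep("C", 10), rep("A", L - 10)), collapse = "")
  aln2 <- dna_alignment(c(a1 = a, a2 = c1, b1 = b), "t")
  part2 <- tibble::tibble(specimen_id = c("a1", "a2", "b1"),
                          group = c("A", "A", "B"))
  nets2 <- build_networks(collapse_haplotypes(aln2), fixed_steps = 3)
  sA2 <- network_separation(nets2, part2, "A")
  expect_true(sA2$is_separate)
  expect_equal(sA2$n_networks_spanned, 2L)

  # two groups joined in one network at 2 steps
  near <- paste(c(rep("A", L - 2), "T", "T"), collapse = "")
  aln3 <- dna_alignment(c(x1 = a, x2 = a, y1 = near, y2 = near), "t")
  part3 <- tibble::tibble(specimen_id = c("x1", "x2", "y1", "y2"),
                          group = c("X", "X", "Y", "Y"))
  nets3 <- build_networks(collapse_haplotypes(aln3), fixed_steps = 5)
  sX <- network_separation(nets3, part3, "X")
  expect_false(sX$is_separate)
  expect_equal(sX$min_steps_to_nonmember, 2)

  # group absent from the locus
  s0 <- network_separation(nets3, dplyr::bind_rows(
    part3, tibble::tibble(specimen_id = "zz", group = "Z")), "Z")
  expect_false(s0$has_data)
})

test_that("network count does not increase when the probability limit is relaxed", {
  set.seed(121)
  for (rep in 1:5) {
    cl <- rand_clustered_alignment(4, 4, 150, within_mut = 0.02)
    haps <- collapse_haplotypes(cl$aln)
    n98 <- n_networks(build_networks(haps, connection_limit(150, 0.98)))
    n90 <- n_networks(build_networks(haps, connection_limit(150, 0.90)))
    expect_lte(n90, n98)
  }
})
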