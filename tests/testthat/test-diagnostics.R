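test_that("alignment-to-sequence coordinate mapping counts non-gap prefix", {
  aln <- dna_alignment(c(r = "--ACGT", s = "TTACGT"), "t")
  expect_equal(map_alignment_position(aln, "s", 3), 3L)   # gapless row
  expect_equal(map_alignment_position(aln, "r", 3), 1L)   # leading gaps
  expect_error(map_alignment_position(aln, "r", 1), "gap")
  expect_error(map_alignment_position(aln, "r", 9), "outside")

  set.seed(131)
  for (rep in 1:20) {
    aln <- rand_alignment(1, 40, p_gap = 0.3, p_missing = 0)
    row <- unclass(aln)[1, ]
    pos <- which(row != "-")
    if (!length(pos)) next
    p <- sample(pos, 1)
    # linear-scan oracle
    expect_equal(map_alignment_position(aln, rownames(aln)[1], p),
                 sum(row[1:p] != "-"))
  }
})

test_that("diagnostic columns: fixed differences yes, polymorphism no", {
  m <- rbind(
    A1 = strsplit("AACGTACGTA", "")[[1]],
    A2 = strsplit("AACGTACGTA", "")[[1]],
    B1 = strsplit("AGCGTACGTA", "")[[1]],
    B2 = strsplit("AGCGTACGTA", "")[[1]]
  )
  # column 2: A fixed in species A, G fixed in species B -> diagnostic both ways
  aln <- dna_alignment(m, "t")
  part <- tibble::tibble(specimen_id = rownames(m),
                         group = c("A", "A", "B", "B"))
  dA <- diagnostic_positions(aln, part, "A")
  expect_equal(dA$aln_start, 2L)
  expect_equal(dA$state, "A")
  expect_equal(dA$ref_start, 2L)
  dB <- diagnostic_positions(aln, part, "B")
  expect_equal(dB$state, "G")

  # focal polymorphism kills the column
  m2 <- m; m2["A2", 2] <- "G"
  d2 <- diagnostic_positions(dna_alignment(m2, "t"), part, "A")
  expect_equal(nrow(d2), 0L)

  # focal missing blocks the column under the strict policy
  m3 <- m; m3["A2", 2] <- "N"
  d3 <- diagnostic_positions(dna_alignment(m3, "t"), part, "A")
  expect_equal(nrow(d3), 0L)
})

test_that("insert diagnostics report ranges in dual coordinates", {
  m <- rbind(
    F1 = strsplit("AATCTCTGG", "")[[1]],
    F2 = strsplit("AATCTCTGG", "")[[1]],
    O1 = strsplit("AA-----GG", "")[[1]],
    O2 = strsplit("AA-----GG", "")[[1]]
  )
  # give the reference a leading gap to decouple coordinates
  m <- cbind(`1` = c("-", "A", "A", "A"), m)
  rownames(m) <- c("F1", "F2", "O1", "O2")
  aln <- dna_alignment(m, "t")
  part <- tibble::tibble(specimen_id = rownames(m),
                         group = c("F", "F", "O", "O"))
  d <- diagnostic_positions(aln, part, "F", ref_id = "F1")
  ins <- d[d$kind == "insert", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$aln_start, 4L)
  expect_equal(ins$aln_end, 8L)
  expect_equal(ins$state, "TCTCT")
  expect_equal(ins$ref_start, 3L)    # F1 has a gap at column 1
  expect_equal(ins$ref_end, 7L)

  # base-vs-gap single columns in the non-focal species are substitutions
  # viewed from the focal side; the complement species has no insert
  dO <- diagnostic_positions(aln, part, "O", ref_id = "O1")
  expect_equal(nrow(dO[dO$kind == "insert", ]), 0L)
})

test_that("diagnostics match the exhaustive column scan on constructed toys", {
  set.seed(141)
  for (rep in 1:20) {
    cl <- rand_clustered_alignment(4, 3, 12, between_mut = 0.4,
                                   within_mut = 0.05)
    for (g in unique(cl$truth$group)) {
      got <- diagnostic_positions(cl$aln, cl$truth, g)
      got_sub <- got[got$kind == "substitution", ]
      want <- oracle_diagnostic_columns(cl$aln, cl$truth, g)
      expect_equal(got_sub$aln_start, want$aln_start)
      expect_equal(got_sub$state, want$state)
    }
  }
})

test_that("every reported diagnostic survives a post-hoc soundness rescan", {
  set.seed(151)
  cl <- rand_clustered_alignment(5, 4, 60, between_mut = 0.3)
  m <- unclass(cl$aln)
  part <- setNames(cl$truth$group, cl$truth$specimen_id)
  for (g in unique(part)) {
    d <- diagnostic_positions(cl$aln, cl$truth, g)
    for (k in seq_len(nrow(d))) {
      cols <- d$aln_start[k]:d$aln_end[k]
      states <- strsplit(d$state[k], "")[[1]]
      foc <- m[part[rownames(m)] == g, cols, drop = FALSE]
      oth <- m[part[rownames(m)] != g, cols, drop = FALSE]
      for (ci in seq_along(cols)) {
        expect_true(all(foc[, ci] == states[ci]))
        res <- oth[, ci][oth[, ci] %in% c("A", "C", "G", "T", "-")]
        expect_false(any(res == states[ci]))
      }
    }
  }
})

test_that("adding non-focal sequences never adds diagnostics", {
  set.seed(161)
  for (rep in 1:10) {
    cl <- rand_clustered_alignment(3, 3, 30, between_mut = 0.3)
    g <- "grp1"
    before <- diagnostic_positions(cl$aln, cl$truth, g)
    # new non-focal specimen: a mutated copy of a grp2 sequence
    m <- unclass(cl$aln)
    donor <- cl$truth$specimen_id[cl$truth$group == "grp2"][1]
    newrow <- m[donor, ]
    hit <- sample(length(newrow), 3)
    newrow[hit] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    m2 <- rbind(m, added = newrow)
    truth2 <- dplyr::bind_rows(cl$truth,
                               tibble::tibble(specimen_id = "added",
                                              group = "grp2"))
    after <- diagnostic_positions(dna_alignment(m2, "t"), truth2, g)
    key <- function(d) paste(d$aln_start, d$aln_end, d$state)
    expect_true(all(key(after) %in% key(before)))
  }
})

test_that("diagnostics are invariant under specimen reordering and ref checks work", {
  set.seed(171)
  cl <- rand_clustered_alignment(3, 4, 40, between_mut = 0.3)
  g <- "grp2"
  ref <- cl$truth$specimen_id[cl$truth$group == g][2]
  d1 <- diagnostic_positions(cl$aln, cl$truth, g, ref_id = ref)
  perm <- sample(nrow(cl$aln))
  aln2 <- dna_alignment(unclass(cl$aln)[perm, ], "t")
  d2 <- diagnostic_positions(aln2, cl$truth, g, ref_id = ref)
  expect_equal(d1[, -2], d2[, -2])  # locus name differs, content equal
  expect_error(diagnostic_positions(cl$aln, cl$truth, g, ref_id = "c01"),
               "not in species")
})

test_that("diagnostic_table prefers the holotype as reference", {
  sim <- simulate_dataset(sim_config(n_species = 3, specimens_per_species = 3,
                                     seed = 41))
  tab <- diagnostic_table(sim$dataset, sim$truth$partition)
  expect_true(all(c("species", "locus", "aln_start", "ref_start",
                    "state", "kind") %in% names(tab)))
  # at least one species carries a diagnostic at some locus in a deep tree
  expect_gt(nrow(tab), 0)
})
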