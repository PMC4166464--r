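# Independent brute-force oracles, coded against the same definitions as the
# package but through character-set logic rather than bitmasks, plus random
# instance generators.  These stay deliberately naive.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G")
)
is_missing_chr <- function(ch) ch %in% c("N", "?")
is_base_chr <- function(ch) ch %in% names(iupac_sets)

rand_alignment <- function(n, L, p_gap = 0.05, p_missing = 0.05,
                           p_ambig = 0.03, locus = "toy") {
  pool_base <- c("A", "C", "G", "T")
  pool_ambig <- setdiff(names(iupac_sets), pool_base)
  m <- matrix(sample(pool_base, n * L, replace = TRUE), n, L)
  k <- n * L
  hit <- runif(k) < p_ambig
  m[hit] <- sample(pool_ambig, sum(hit), replace = TRUE)
  hit <- runif(k) < p_gap
  m[hit] <- "-"
  hit <- runif(k) < p_missing
  m[hit] <- sample(c("N", "?"), sum(hit), replace = TRUE)
  rownames(m) <- sprintf("s%02d", seq_len(n))
  dna_alignment(m, locus_name = locus)
}

# clustered alignment: groups of near-identical sequences separated by many
# fixed differences (for discovery / separation checks)
rand_clustered_alignment <- function(n_groups, per_group, L,
                                     between_mut = 0.25, within_mut = 0.01) {
  pool <- c("A", "C", "G", "T")
  rows <- list(); grp <- character(0)
  for (g in seq_len(n_groups)) {
    proto <- sample(pool, L, replace = TRUE)
    if (g > 1) {
      # ensure distinctness from earlier prototypes by fresh draw + forced muts
      hit <- runif(L) < between_mut
      proto[hit] <- sample(pool, sum(hit), replace = TRUE)
    }
    for (i in seq_len(per_group)) {
      s <- proto
      hit <- runif(L) < within_mut
      s[hit] <- sample(pool, sum(hit), replace = TRUE)
      rows[[length(rows) + 1L]] <- s
      grp <- c(grp, paste0("grp", g))
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("c%02d", seq_along(rows))
  list(aln = dna_alignment(m),
       truth = tibble::tibble(specimen_id = rownames(m), group = grp))
}

chars_match <- function(a, b) {
  # overlap policy; gap only matches gap; missing handled by caller
  if (a == "-" || b == "-") return(a == b)
  length(intersect(iupac_sets[[a]], iupac_sets[[b]])) > 0
}

oracle_p_distance <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  d <- matrix(0, n, n); comp <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    nc <- 0L; mm <- 0L
    for (col in seq_len(ncol(m))) {
      a <- m[i, col]; b <- m[j, col]
      if (a == "-" || b == "-" || is_missing_chr(a) || is_missing_chr(b)) next
      nc <- nc + 1L
      if (!chars_match(a, b)) mm <- mm + 1L
    }
    comp[i, j] <- comp[j, i] <- nc
    val <- if (nc == 0L) NA_real_ else mm / nc
    d[i, j] <- d[j, i] <- val
  }
  dimnames(d) <- dimnames(comp) <- list(rownames(m), rownames(m))
  list(distance = d, comparable_sites = comp)
}

oracle_step_distance <- function(x, y) {
  steps <- 0L
  for (col in seq_along(x)) {
    a <- x[col]; b <- y[col]
    if (is_missing_chr(a) || is_missing_chr(b)) next
    if (!chars_match(a, b)) steps <- steps + 1L
  }
  steps
}

oracle_haplotype_count <- function(aln) {
  m <- unclass(aln)
  reps <- list()
  for (i in seq_len(nrow(m))) {
    found <- FALSE
    for (r in reps) {
      same <- TRUE
      for (col in seq_len(ncol(m))) {
        a <- r[col]; b <- m[i, col]
        if (is_missing_chr(a) || is_missing_chr(b)) next
        if (!chars_match(a, b)) { same <- FALSE; break }
      }
      if (same) { found <- TRUE; break }
    }
    if (!found) reps[[length(reps) + 1L]] <- m[i, ]
  }
  length(reps)
}

# connected components of the thresholded step graph, by hand-rolled BFS
oracle_components <- function(step_matrix, j_max) {
  k <- nrow(step_matrix)
  comp <- rep(NA_integer_, k)
  cur <- 0L
  for (start in seq_len(k)) {
    if (!is.na(comp[start])) next
    cur <- cur + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(step_matrix[v, ] <= j_max & is.na(comp))
      queue <- c(queue, setdiff(nb, v))
    }
  }
  setNames(comp, rownames(step_matrix))
}

# diagnostics: exhaustive column scan (substitution characters only)
oracle_diagnostic_columns <- function(aln, partition, focal) {
  m <- unclass(aln)
  part <- setNames(partition$group, partition$specimen_id)
  foc <- m[part[rownames(m)] == focal, , drop = FALSE]
  oth <- m[part[rownames(m)] != focal, , drop = FALSE]
  out <- integer(0); states <- character(0)
  for (col in seq_len(ncol(m))) {
    fs <- unique(foc[, col])
    if (length(fs) != 1L || !fs %in% c("A", "C", "G", "T")) next
    os <- oth[, col]
    os <- os[os %in% c("A", "C", "G", "T", "-")]  # resolved others
    if (any(os == fs)) next
    # skip pure-insert columns (all resolved others gapped)
    if (length(os) && all(os == "-")) next
    out <- c(out, col); states <- c(states, fs)
  }
  tibble::tibble(aln_start = out, state = states)
}

# Tajima 1989 via the site-frequency formulation (independent of the
# pairwise-difference code path)
oracle_tajima <- function(aln) {
  m <- unclass(aln)
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- 0L; pi <- 0
  for (col in seq_len(ncol(m))) {
    counts <- table(m[, col])
    if (length(counts) > 1L) S <- S + 1L
    pi <- pi + (choose(n, 2) - sum(choose(counts, 2))) / choose(n, 2)
  }
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  if (S == 0) return(list(S = 0L, D = NA_real_))
  list(S = S, pi = pi,
       D = (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)))
}

# connection limit recomputed numerically: theta recovered by root finding
# on the Jukes-Cantor saturation curve instead of the closed form
oracle_j_max <- function(L, prob_limit) {
  p_of_theta <- function(th) 0.75 * (1 - exp(-4 * th / 3))
  j <- 0L
  repeat {
    jj <- j + 1L
    p <- jj / L
    if (p >= 0.75) break
    th <- uniroot(function(th) p_of_theta(th) - p, c(1e-12, 100),
                  tol = 1e-13)$root
    pr <- exp(jj * (log(th) - log(p) - th))
    if (pr < prob_limit) break
    j <- jj
    if (j >= L) break
  }
  j
}

# neutral coalescent alignment for popstats checks
rand_neutral_alignment <- function(n = 20, L = 1000, rate = 0.005) {
  tr <- ape::rcoal(n)
  m <- toupper(as.character(phangorn::simSeq(tr, l = L, rate = rate)))
  dna_alignment(m)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# TRUE iff two labelings induce the same partition (robust to the ARI's
# undefined value when both sides are a single cluster)
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

partition_of <- function(result) {
  setNames(result$partition$group, result$partition$specimen_id)
}

compare_partitions <- function(p1, p2) {
  ids <- intersect(p1$specimen_id, p2$specimen_id)
  a <- setNames(p1$group, p1$specimen_id)[ids]
  b <- setNames(p2$group, p2$specimen_id)[ids]
  ari(a, b)
}
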