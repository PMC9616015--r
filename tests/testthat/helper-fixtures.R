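# Fixture builders and independent naive-loop oracles used across the suite.
# Oracles deliberately use explicit element loops so they share no code path
# with the package implementations they check.

rand_sym_matrix <- function(n, p = 0.3, ids = sprintf("o%02d", seq_len(n))) {
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) m[i, j] <- m[j, i] <- 1L
  m
}

rand_directed_matrix <- function(n, p = 0.3,
                                 ids = sprintf("o%02d", seq_len(n))) {
  m <- matrix(rbinom(n * n, 1, p), n, n, dimnames = list(ids, ids))
  storage.mode(m) <- "integer"
  diag(m) <- 0L
  m
}

make_report_matrix <- function(mat, responded = NULL, layer = "contact") {
  ids <- rownames(mat)
  if (is.null(responded)) responded <- rep(TRUE, nrow(mat))
  names(responded) <- ids
  mat[!responded, ] <- 0L
  new("ReportMatrix", mat = mat, responded = responded,
      reconstructed = matrix(FALSE, nrow(mat), ncol(mat),
                             dimnames = dimnames(mat)),
      layer = layer)
}

tiny_roster <- function(n, sectors = rep("education", n),
                        tasks = rep("signaling", n)) {
  ids <- sprintf("o%02d", seq_len(n))
  Roster(org_id = ids, sector = sectors, tasks = tasks,
         respondent_ids = paste0(ids, "_r1"))
}

star_matrix <- function(n) {
  ids <- sprintf("o%02d", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  m[1, 2:n] <- 1L
  m[2:n, 1] <- 1L
  m
}

cycle_matrix <- function(n) {
  ids <- sprintf("o%02d", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    m[i, j] <- m[j, i] <- 1L
  }
  m
}

complete_matrix <- function(n) {
  ids <- sprintf("o%02d", seq_len(n))
  m <- matrix(1L, n, n, dimnames = list(ids, ids))
  diag(m) <- 0L
  m
}

# a symmetric graph with exactly `edges` undirected edges on n nodes,
# filling the upper triangle row by row
graph_with_edges <- function(n, edges, ids = sprintf("o%03d", seq_len(n))) {
  stopifnot(edges <= n * (n - 1) / 2)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  left <- edges
  for (i in seq_len(n - 1)) {
    if (left == 0) break
    take <- min(left, n - i)
    if (take > 0) {
      m[i, (i + 1):(i + take)] <- 1L
      m[(i + 1):(i + take), i] <- 1L
      left <- left - take
    }
  }
  m
}

## ---- naive oracles ----

naive_ties <- function(m) {
  total <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if (i != j && m[i, j] == 1L) total <- total + 1L
  total
}

naive_density <- function(m) {
  n <- nrow(m)
  naive_ties(m) / (n * (n - 1))
}

naive_avg_degree <- function(m) naive_ties(m) / nrow(m)

naive_degrees <- function(m) {
  deg <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    d <- 0L
    for (j in seq_len(ncol(m))) if (j != i && m[i, j] == 1L) d <- d + 1L
    deg[i] <- d
  }
  names(deg) <- rownames(m)
  deg
}

naive_isolates <- function(m) sum(naive_degrees(m) == 0)

naive_centralization <- function(m) {
  deg <- naive_degrees(m)
  n <- nrow(m)
  dmax <- max(deg)
  total <- 0
  for (i in seq_len(n)) total <- total + (dmax - deg[[i]])
  total / ((n - 1) * (n - 2))
}

naive_symmetrize <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    out[i, j] <- max(m[i, j], m[j, i])
  diag(out) <- 0L
  storage.mode(out) <- "integer"
  out
}

# OR over per-respondent incidence matrices, by brute-force loop
naive_collapse <- function(records, roster_ids, layer) {
  n <- length(roster_ids)
  m <- matrix(0L, n, n, dimnames = list(roster_ids, roster_ids))
  for (r in seq_len(nrow(records))) {
    if (records$layer[r] != layer) next
    m[records$reporter_org[r], records$target_org[r]] <- 1L
  }
  diag(m) <- 0L
  m
}

# between- and within-sector tie fractions by explicit pair loop
naive_sector_fractions <- function(m, sec) {
  ids <- rownames(m)
  sectors <- sort(unique(sec))
  res <- list()
  for (a in seq_along(sectors)) for (b in seq_along(sectors)) {
    if (a > b) next
    poss <- 0L; pres <- 0L
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i) next
      si <- sec[ids[i]]; sj <- sec[ids[j]]
      pair_ok <- (si == sectors[a] && sj == sectors[b]) ||
        (si == sectors[b] && sj == sectors[a])
      if (pair_ok) {
        poss <- poss + 1L
        if (m[i, j] == 1L) pres <- pres + 1L
      }
    }
    res[[paste(sectors[a], sectors[b], sep = "|")]] <-
      c(possible = poss, present = pres)
  }
  res
}

# every labeled graph on n nodes, as a list of adjacency matrices
all_graphs <- function(n) {
  npairs <- n * (n - 1) / 2
  ids <- sprintf("o%02d", seq_len(n))
  lapply(0:(2^npairs - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(npairs)]
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- bits
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  })
}
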