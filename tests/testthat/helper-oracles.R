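# Independent oracles used to cross-check the package implementations.
# Everything here is deliberately written as plain loops / enumeration,
# sharing no code path with the package.

# random directed binary web
rand_web <- function(S, p = 0.3, p_self = 0.1, month = 1) {
  nodes <- paste0("n", seq_len(S))
  pairs <- expand.grid(resource = nodes, consumer = nodes,
                       stringsAsFactors = FALSE)
  self <- pairs$resource == pairs$consumer
  keep <- ifelse(self, stats::runif(nrow(pairs)) < p_self,
                 stats::runif(nrow(pairs)) < p)
  monthly_web(month, nodes, pairs[keep, , drop = FALSE])
}

# random layered (acyclic, grounded) web: nodes in levels, links only from
# strictly lower levels
rand_layered_web <- function(n_per_level = c(5, 15, 20, 10), p = 0.3) {
  lev <- rep(seq_along(n_per_level), n_per_level)
  nodes <- paste0("n", seq_along(lev))
  links <- NULL
  for (i in seq_along(nodes)) {
    if (lev[i] == 1) next
    cand <- nodes[lev < lev[i]]
    pick <- cand[stats::runif(length(cand)) < p]
    if (!length(pick)) pick <- sample(cand, 1)
    links <- rbind(links, data.frame(resource = pick, consumer = nodes[i],
                                     stringsAsFactors = FALSE))
  }
  monthly_web(1, nodes, links)
}

# adjacency matrix A[resource, consumer]
web_adj <- function(web) {
  S <- length(web$nodes)
  A <- matrix(0, S, S, dimnames = list(web$nodes, web$nodes))
  for (i in seq_len(nrow(web$links)))
    A[web$links$resource[i], web$links$consumer[i]] <- 1
  A
}

# prey-averaged trophic levels by synchronous fixed-point iteration,
# restricted to nodes with a diet path to a basal node
oracle_tl <- function(web, n_iter = 10000) {
  A <- web_adj(web)
  diag(A) <- 0
  nodes <- web$nodes
  basal <- colSums(A) == 0
  grounded <- basal
  repeat {
    new <- grounded
    for (n in nodes[!grounded]) {
      res <- nodes[A[, n] == 1]
      if (any(grounded[res])) new[n] <- TRUE
    }
    if (identical(new, grounded)) break
    grounded <- new
  }
  tl <- ifelse(grounded, 1, NA_real_)
  names(tl) <- nodes
  for (it in seq_len(n_iter)) {
    tl_new <- tl
    for (n in nodes[grounded & !basal]) {
      res <- nodes[A[, n] == 1]
      res <- res[grounded[res]]
      tl_new[n] <- 1 + mean(tl[res])
    }
    if (max(abs(tl_new - tl), na.rm = TRUE) < 1e-12) break
    tl <- tl_new
  }
  tl
}

# brute-force descriptor panel (loops + BFS), mirroring the documented
# definitions
oracle_descriptors <- function(web) {
  A <- web_adj(web)
  nodes <- web$nodes
  S <- length(nodes)
  L <- sum(A)
  A0 <- A; diag(A0) <- 0
  nres0 <- colSums(A0); ncons0 <- rowSums(A0)
  class <- ifelse(nres0 == 0, "basal",
                  ifelse(ncons0 == 0, "top", "intermediate"))
  tl <- oracle_tl(web)
  omn <- vapply(nodes, function(n) {
    lv <- round(tl[nodes[A0[, n] == 1]])
    length(unique(lv[!is.na(lv)])) >= 2
  }, logical(1))
  cann <- diag(A) == 1
  LD <- L / S
  nres <- colSums(A); ncons <- rowSums(A)
  gen <- nres[nres > 0] / LD
  vul <- ncons[ncons > 0] / LD
  sd0 <- function(x) if (length(x) >= 2) stats::sd(x) else 0
  mean0 <- function(x) if (length(x)) mean(x) else 0

  U <- (A0 + t(A0)) > 0
  dist <- matrix(Inf, S, S)
  for (s in seq_len(S)) {
    dist[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (f in frontier) for (t in which(U[f, ]))
        if (dist[s, t] > d) { dist[s, t] <- d; nxt <- c(nxt, t) }
      frontier <- unique(nxt)
    }
  }
  finite <- is.finite(dist) & row(dist) != col(dist)
  cpl <- if (any(finite)) mean(dist[finite]) else NA_real_
  cc_vals <- c()
  for (i in seq_len(S)) {
    nb <- which(U[i, ])
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    closed <- sum(U[cbind(pairs[1, ], pairs[2, ])])
    cc_vals <- c(cc_vals, closed / ncol(pairs))
  }
  cc <- if (length(cc_vals)) mean(cc_vals) else 0

  c(S = S, L = L, LD = LD, C = L / S^2,
    frac_top = mean(class == "top"),
    frac_intermediate = mean(class == "intermediate"),
    frac_basal = mean(class == "basal"),
    frac_omnivore = mean(omn), frac_cannibal = mean(cann),
    gen_mean = mean0(gen), gen_sd = sd0(gen),
    vul_mean = mean0(vul), vul_sd = sd0(vul),
    mean_TL = mean(tl, na.rm = TRUE), max_TL = max(tl, na.rm = TRUE),
    cpl = cpl, cc = cc)
}

# exact two-group Kruskal-Wallis permutation distribution via combn and
# stats::kruskal.test on every assignment
oracle_kw_exact2 <- function(a, b) {
  x <- c(a, b)
  n <- length(x)
  obs <- stats::kruskal.test(x, factor(rep(1:2, c(length(a), length(b)))))$statistic
  idx <- utils::combn(n, length(a), simplify = FALSE)
  hs <- vapply(idx, function(i) {
    g <- factor(ifelse(seq_len(n) %in% i, 1, 2))
    unname(stats::kruskal.test(x, g)$statistic)
  }, numeric(1))
  list(H = unname(obs), p = mean(hs >= unname(obs) - 1e-12))
}

# tiny sample-record data.frame builder
make_samples <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(taxon_id = r[[1]], group = r[[2]], year = as.integer(r[[3]]),
               month = as.integer(r[[4]]), abundance = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)))
}
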