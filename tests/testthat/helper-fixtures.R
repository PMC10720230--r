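# Shared fixtures and independent oracles, all built in code.

# quick cohort: codes is a list of character vectors
makeCohort <- function(codes, ages = NULL, sexes = NULL, label = "test") {
  n <- length(codes)
  if (is.null(ages)) ages <- rep(45L, n)
  if (is.null(sexes)) sexes <- rep(c("male", "female"), length.out = n)
  Cohort(data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    age = ages, sex = sexes, stringsAsFactors = FALSE),
         codes, label = label)
}

# admission records data.frame in the shape readRecords() produces
makeRecords <- function(ids, dates, ages, sexes, codes) {
  out <- data.frame(patient_id = ids, age = as.integer(ages),
                    sex = sexes, stringsAsFactors = FALSE)
  out$admission_date <- as.Date(dates)
  out$codes <- I(codes)
  out
}

# network directly from an edge list (codes), all ORs > 1
netFromEdges <- function(edges, frequency = NULL, label = "toy") {
  if (is.null(frequency)) frequency <- rep(1, nrow(edges))
  pat <- data.frame(code_i = pmin(edges[, 1], edges[, 2]),
                    code_j = pmax(edges[, 1], edges[, 2]),
                    odds_ratio = rep(2, nrow(edges)),
                    p_value = rep(1e-6, nrow(edges)),
                    frequency = frequency,
                    selected = rep(TRUE, nrow(edges)),
                    stringsAsFactors = FALSE)
  buildNetwork(pat, label = label)
}

# Erdos-Renyi edge list over nodes N01..Nnn (deterministic given seed)
randomEdges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

# --- brute-force clique oracle (subset enumeration, n <= 15) -------------
# adjacency from an edge list
adjFromEdges <- function(nodes, edges) {
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    A[cbind(edges[, 1], edges[, 2])] <- TRUE
    A[cbind(edges[, 2], edges[, 1])] <- TRUE
  }
  A
}

isClique <- function(A, idx) {
  if (length(idx) < 2L) return(TRUE)
  all(A[idx, idx][upper.tri(diag(length(idx)))])
}

# all maximal cliques by exhaustive subset search
bruteMaximalCliques <- function(A) {
  n <- nrow(A)
  subsets <- lapply(seq_len(2^n) - 1L, function(m) which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0))
  cliques <- Filter(function(s) length(s) > 0 && isClique(A, s), subsets)
  maximal <- Filter(function(s) {
    extra <- setdiff(seq_len(n), s)
    !any(vapply(extra, function(v) isClique(A, c(s, v)), logical(1)))
  }, cliques)
  lapply(maximal, function(s) sort(rownames(A)[s]))
}

bruteMCC <- function(A, node) {
  cl <- bruteMaximalCliques(A)
  cl <- Filter(function(C) length(C) >= 2 && node %in% C, cl)
  sum(vapply(cl, function(C) factorial(length(C) - 1L), numeric(1)))
}

# --- independent metric oracles ------------------------------------------
# power-iteration pagerank on an adjacency matrix
brutePagerank <- function(A, d = 0.85, tol = 1e-12) {
  n <- nrow(A)
  deg <- rowSums(A)
  x <- rep(1 / n, n)
  repeat {
    inflow <- as.vector(t(A) %*% ifelse(deg > 0, x / deg, 0))
    dangling <- sum(x[deg == 0]) / n
    x_new <- (1 - d) / n + d * (inflow + dangling)
    if (max(abs(x_new - x)) < tol) break
    x <- x_new
  }
  setNames(x_new / sum(x_new), rownames(A))
}

# brute-force betweenness by enumerating all shortest paths (tiny graphs)
bruteBetweenness <- function(A) {
  n <- nrow(A)
  g_paths <- function(s, t) {
    # BFS shortest path enumeration
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    preds <- vector("list", n)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(A[v, ])) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1; queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) preds[[w]] <- union(preds[[w]], v)
      }
    }
    if (is.infinite(dist[t])) return(list())
    walk <- function(v) {
      if (v == s) return(list(s))
      unlist(lapply(preds[[v]], function(p)
        lapply(walk(p), function(pa) c(pa, v))), recursive = FALSE)
    }
    walk(t)
  }
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- g_paths(s, t)
    if (!length(paths)) next
    for (pa in paths) {
      inner <- setdiff(pa, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(paths)
    }
  }
  setNames(btw, rownames(A))
}

# cross-product odds ratio + Wald p via an actual logistic regression fit
glmOracle <- function(n11, n10, n01, n00) {
  x <- c(rep(1, n11 + n10), rep(0, n01 + n00))
  y <- c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  fit <- suppressWarnings(glm(y ~ x, family = binomial(),
                              control = glm.control(epsilon = 1e-12,
                                                    maxit = 100)))
  s <- summary(fit)$coefficients
  c(or = exp(unname(coef(fit)["x"])), p = unname(s["x", "Pr(>|z|)"]))
}

# 1-D root search oracle for the joint prevalence given an odds ratio
bruteJointPrevalence <- function(p_i, p_j, psi, tol = 1e-12) {
  f <- function(p11) {
    p10 <- p_i - p11; p01 <- p_j - p11; p00 <- 1 - p_i - p_j + p11
    (p11 * p00) / (p10 * p01) - psi
  }
  lo <- max(0, p_i + p_j - 1) + 1e-12
  hi <- min(p_i, p_j) - 1e-12
  uniroot(f, c(lo, hi), tol = tol)$root
}
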