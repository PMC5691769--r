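# Sex-weighted Spearman correlation network, maximum-spanning-tree pruning,
# greedy-modularity module detection, and per-module PC scores.

new_correlation_network <- function(nodes, edges, pruned = FALSE) {
  structure(list(nodes = nodes, edges = edges, pruned = pruned),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation_network:", length(x$nodes), "nodes,", nrow(x$edges),
      if (x$pruned) "edges (pruned)\n" else "edges\n")
  invisible(x)
}

#' Sex-weighted Spearman correlation network
#'
#' Spearman correlations between all variable pairs, estimated separately
#' within women and men (pairwise-complete observations) and combined as
#' `w_f * rho_f + w_m * rho_m` with weights equal to the sex fractions. A
#' variable constant within a sex contributes a zero correlation for that
#' sex (with a warning).
#'
#' @param data numeric matrix/data.frame, participants x variables
#' @param sex `"female"`/`"male"` per participant
#' @return a `correlation_network` with an edge per unordered variable pair
#' @export
sex_weighted_spearman <- function(data, sex) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(sex), ncol(data) >= 2)
  sexes <- intersect(cohort_vocab$sex, unique(sex))
  combined <- matrix(0, ncol(data), ncol(data),
                     dimnames = list(colnames(data), colnames(data)))
  for (s in sexes) {
    rows <- sex == s
    if (sum(rows) < 3) stop_validation("need >= 3 participants per sex")
    block <- data[rows, , drop = FALSE]
    constant <- apply(block, 2, function(x) sd(x, na.rm = TRUE) == 0 ||
                        all(is.na(x)))
    if (any(constant))
      warning("variable(s) constant within sex '", s, "': ",
              paste(colnames(data)[constant], collapse = ", "),
              "; their correlations set to 0")
    rho <- suppressWarnings(
      cor(block, method = "spearman", use = "pairwise.complete.obs"))
    rho[is.na(rho)] <- 0
    combined <- combined + (sum(rows) / nrow(data)) * rho
  }
  pairs <- which(upper.tri(combined), arr.ind = TRUE)
  edges <- data.frame(
    u = colnames(data)[pairs[, 1]], v = colnames(data)[pairs[, 2]],
    weight = combined[pairs], stringsAsFactors = FALSE)
  new_correlation_network(colnames(data), edges)
}

#' Prune a correlation network to its maximum spanning forest
#'
#' Kruskal's algorithm on absolute edge weights: within every connected
#' component only the spanning tree with the largest total |weight| is
#' retained (the "strongest connection" skeleton). Deterministic tie-break:
#' edges sorted by decreasing |weight|, then by `u`, then `v` labels.
#' Invariant to flipping the sign of every correlation.
#'
#' @param network a `correlation_network`
#' @return the pruned `correlation_network` (`pruned = TRUE`)
#' @export
prune_spanning_tree <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  edges <- network$edges
  if (nrow(edges) == 0) return(new_correlation_network(network$nodes, edges, TRUE))
  ord <- order(-abs(edges$weight), edges$u, edges$v)
  edges <- edges[ord, , drop = FALSE]
  parent <- setNames(seq_along(network$nodes), network$nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    ru <- find(match(edges$u[e], network$nodes))
    rv <- find(match(edges$v[e], network$nodes))
    if (ru != rv) {
      parent[ru] <- rv
      keep[e] <- TRUE
    }
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_correlation_network(network$nodes, out, TRUE)
}

#' Detect variable modules by greedy modularity agglomeration
#'
#' Agglomerative (Clauset-Newman-Moore-style) community detection on
#' absolute edge weights: starting from singletons, repeatedly merges the
#' connected pair of communities with the largest modularity gain until no
#' merge improves modularity. Ties are broken lexicographically on the
#' smallest member label of the merged pair, making the procedure
#' deterministic. The returned partition's modularity is never below that
#' of the all-singletons partition.
#'
#' @param network a (pruned) `correlation_network`
#' @return a `module_set` with `assignment` (named module id per variable,
#'   numbered by smallest member label) and empty scores
#' @export
detect_modules <- function(network) {
  stopifnot(inherits(network, "correlation_network"))
  nodes <- network$nodes
  w <- abs(network$edges$weight)
  comm <- setNames(seq_along(nodes), nodes)
  if (length(nodes) > 1 && nrow(network$edges) > 0 && sum(w) > 0) {
    eu <- match(network$edges$u, nodes)
    ev <- match(network$edges$v, nodes)
    m <- sum(w)  # total (undirected) edge weight
    repeat {
      cu <- comm[eu]; cv <- comm[ev]
      strength <- tapply(c(w, w), c(cu, cv), sum)  # per-community strength
      between <- tapply(w, paste(pmin(cu, cv), pmax(cu, cv)), sum)
      pair_ids <- strsplit(names(between), " ", fixed = TRUE)
      best <- NULL; best_dq <- 0; best_key <- ""
      for (i in seq_along(pair_ids)) {
        a <- pair_ids[[i]][1]; b <- pair_ids[[i]][2]
        if (a == b) next  # internal edges, not a merge candidate
        dq <- between[[i]] / m - strength[[a]] * strength[[b]] / (2 * m^2)
        if (dq <= 1e-12) next
        key <- min(names(comm)[comm %in% as.integer(c(a, b))])
        if (is.null(best) || dq > best_dq + 1e-12 ||
            (abs(dq - best_dq) <= 1e-12 && key < best_key)) {
          best <- as.integer(c(a, b)); best_dq <- dq; best_key <- key
        }
      }
      if (is.null(best)) break
      comm[comm == best[2]] <- best[1]
    }
  }
  # renumber modules 1..k in order of each module's smallest member label
  first <- tapply(names(comm), comm, min)
  ord <- names(first)[order(first)]
  assignment <- setNames(match(as.character(comm), ord), nodes)
  new_module_set(assignment)
}

new_module_set <- function(assignment, scores = NULL, explained_variance = NULL,
                           loadings = NULL, centers = NULL, scales = NULL) {
  structure(list(assignment = assignment, scores = scores,
                 explained_variance = explained_variance,
                 loadings = loadings, centers = centers, scales = scales),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("module_set:", length(unique(x$assignment)), "modules over",
      length(x$assignment), "variables",
      if (is.null(x$scores)) "(no scores)\n" else "(with PC scores)\n")
  invisible(x)
}

#' Per-module principal-component scores
#'
#' For each module, variables are standardized (z-scored, i.e. PCA on the
#' correlation matrix) and the first two principal components are computed.
#' Sign convention: PC1 has a non-negative loading on the module's
#' alphabetically first variable (PC2 likewise). Single-variable modules
#' get PC1 = the z-scored variable and PC2 = 0; zero-variance variables are
#' dropped from their module with a warning.
#'
#' @param data numeric matrix/data.frame with the module variables as
#'   columns and participant ids as rownames
#' @param modules a `module_set` from [detect_modules()]
#' @return the `module_set` with `scores` (matrix participants x
#'   2*modules, columns `M<k>.PC1`, `M<k>.PC2`), per-module
#'   `explained_variance` fractions, and the fitted loadings/centering for
#'   reuse
#' @export
module_scores <- function(data, modules) {
  stopifnot(inherits(modules, "module_set"))
  data <- as.matrix(data)
  missing <- setdiff(names(modules$assignment), colnames(data))
  if (length(missing))
    stop_validation("module variable(s) absent from data: ",
                    paste(missing, collapse = ", "))
  mods <- sort(unique(modules$assignment))
  scores <- matrix(0, nrow(data), 2 * length(mods),
                   dimnames = list(rownames(data),
                                   paste0("M", rep(mods, each = 2), ".PC",
                                          rep(1:2, length(mods)))))
  expl <- list(); loadings <- list(); centers <- list(); scales <- list()
  for (k in mods) {
    vars <- sort(names(modules$assignment)[modules$assignment == k])
    sds <- apply(data[, vars, drop = FALSE], 2, sd)
    if (any(sds == 0)) {
      warning("zero-variance variable(s) dropped from module ", k, ": ",
              paste(vars[sds == 0], collapse = ", "))
      vars <- vars[sds > 0]
    }
    cn <- paste0("M", k, ".PC", 1:2)
    if (length(vars) == 0) { expl[[as.character(k)]] <- c(0, 0); next }
    z <- scale(data[, vars, drop = FALSE])
    if (length(vars) == 1) {
      scores[, cn[1]] <- z[, 1]
      expl[[as.character(k)]] <- c(1, 0)
      loadings[[as.character(k)]] <- matrix(c(1, 0), 1, 2,
                                            dimnames = list(vars, NULL))
    } else {
      pc <- prcomp(z, center = FALSE, scale. = FALSE)
      rot <- pc$rotation[, 1:min(2, ncol(pc$rotation)), drop = FALSE]
      if (ncol(rot) < 2) rot <- cbind(rot, 0)
      for (j in 1:2) if (rot[1, j] < 0) rot[, j] <- -rot[, j]
      sc <- z %*% rot
      scores[, cn] <- sc
      ev <- pc$sdev^2 / sum(pc$sdev^2)
      expl[[as.character(k)]] <- c(ev, 0, 0)[1:2]
      loadings[[as.character(k)]] <- rot
    }
    centers[[as.character(k)]] <- attr(z, "scaled:center")
    scales[[as.character(k)]] <- attr(z, "scaled:scale")
  }
  new_module_set(modules$assignment, scores, expl, loadings, centers, scales)
}

#' Project new participants onto fitted module PC scores
#'
#' @param modules a `module_set` with fitted loadings from [module_scores()]
#' @param data new data with the same variables, rownames = ids
#' @return score matrix in the same column layout as `modules$scores`
#' @export
project_module_scores <- function(modules, data) {
  stopifnot(inherits(modules, "module_set"), !is.null(modules$loadings))
  data <- as.matrix(data)
  mods <- sort(unique(modules$assignment))
  out <- matrix(0, nrow(data), 2 * length(mods),
                dimnames = list(rownames(data), colnames(modules$scores)))
  for (k in as.character(mods)) {
    rot <- modules$loadings[[k]]
    if (is.null(rot)) next
    vars <- rownames(rot)
    z <- scale(data[, vars, drop = FALSE], center = modules$centers[[k]],
               scale = modules$scales[[k]])
    out[, paste0("M", k, ".PC", 1:2)] <- z %*% rot
  }
  out
}
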