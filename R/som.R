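# Self-organizing-map subtyping: sex-rank normalization, batch SOM
# training, best-matching-unit assignment, map coloring, subgroup
# definition, and bootstrap subgroup summaries.

# ---- rank normalization ----------------------------------------------------

#' Rank-normalize variables within sex
#'
#' Splits the data by sex, replaces every continuous variable by its
#' mid-ranks scaled to \[0, 1\] within the sex block, and pools the blocks
#' back together in the original row order. Identical within-sex orderings
#' therefore give identical pooled columns regardless of the raw scales, so
#' sex-driven location/scale differences cannot confound the map. Binary
#' 0/1 variables pass through the same ranking (all-tied values map to
#' 0.5-centred ranks).
#'
#' The returned object stores the per-sex training values so evaluation
#' profiles can be mapped onto the same rank scale by interpolation (values
#' beyond the training range are clamped to 0/1).
#'
#' @param data numeric matrix/data.frame, participants x variables,
#'   rownames = ids
#' @param sex `"female"`/`"male"` per row (>= 2 per sex)
#' @return an object of class `rank_transform` with element `ranked` (the
#'   transformed matrix); transform new data with [apply_rank_transform()]
#' @export
rank_transform_by_sex <- function(data, sex) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(sex))
  all_na <- apply(data, 2, function(x) all(is.na(x)))
  if (any(all_na)) {
    warning("all-missing column(s) excluded: ",
            paste(colnames(data)[all_na], collapse = ", "))
    data <- data[, !all_na, drop = FALSE]
  }
  ranked <- data
  train_values <- list()
  for (s in unique(sex)) {
    rows <- which(sex == s)
    if (length(rows) < 2) stop_validation("need >= 2 participants per sex")
    for (j in seq_len(ncol(data))) {
      x <- data[rows, j]
      r <- rank(x, ties.method = "average", na.last = "keep")
      n_obs <- sum(!is.na(x))
      ranked[rows, j] <- if (n_obs > 1) (r - 1) / (n_obs - 1) else 0.5
      train_values[[s]][[colnames(data)[j]]] <-
        list(x = x[!is.na(x)], r = ranked[rows, j][!is.na(x)])
    }
  }
  structure(list(ranked = ranked, variables = colnames(data),
                 train_values = train_values),
            class = "rank_transform")
}

#' @rdname rank_transform_by_sex
#' @param transform a fitted `rank_transform`
#' @param newdata matrix/data.frame with the transform's variables
#' @param newsex sex per row of `newdata`
#' @export
apply_rank_transform <- function(transform, newdata, newsex) {
  stopifnot(inherits(transform, "rank_transform"))
  newdata <- as.matrix(newdata)[, transform$variables, drop = FALSE]
  out <- newdata
  for (s in unique(newsex)) {
    rows <- which(newsex == s)
    tv <- transform$train_values[[s]]
    if (is.null(tv))
      stop_validation("no training ranks for sex '", s, "'")
    for (j in transform$variables) {
      ref <- tv[[j]]
      if (length(unique(ref$x)) < 2) {
        out[rows, j] <- 0.5
      } else {
        out[rows, j] <- approx(ref$x, ref$r, xout = newdata[rows, j],
                               rule = 2, ties = mean)$y
      }
    }
  }
  out
}

# ---- SOM -------------------------------------------------------------------

# Linear initialization: lay the codebook out on the plane of the first
# two principal components, spanning +/- 2 sd along each. Deterministic and
# invariant to participant order; degenerates gracefully to the data mean
# when the data have (near-)zero variance.
init_codebook_pca <- function(data, g) {
  center <- colMeans(data)
  n_units <- nrow(g$coords)
  axis <- function(v) if (max(v) > min(v)) 2 * (2 * (v - min(v)) / (max(v) - min(v)) - 1) else v * 0
  u1 <- axis(g$coords[, 1]); u2 <- axis(g$coords[, 2])
  cb <- matrix(center, n_units, length(center), byrow = TRUE,
               dimnames = list(NULL, colnames(data)))
  sv <- tryCatch(prcomp(data, center = TRUE, scale. = FALSE), error = function(e) NULL)
  if (!is.null(sv)) {
    for (j in seq_len(min(2, ncol(sv$rotation)))) {
      if (sv$sdev[j] <= 1e-12) next
      dir <- sv$rotation[, j]
      k <- which.max(abs(dir))
      if (dir[k] < 0) dir <- -dir  # sign convention: dominant loading positive
      cb <- cb + outer(if (j == 1) u1 else u2, sv$sdev[j] * dir)
    }
  }
  cb
}

som_grid <- function(width, height) {
  coords <- cbind(x = rep(seq_len(width), times = height),
                  y = rep(seq_len(height), each = width))
  list(width = width, height = height, coords = coords,
       dist2 = as.matrix(stats::dist(coords))^2)
}

#' Train a batch self-organizing map
#'
#' Fits a 2-D rectangular lattice of codebook vectors to (rank-normalized)
#' profiles by batch updates: each epoch assigns every participant to its
#' best-matching unit (BMU) and replaces every codebook vector by the
#' Gaussian-neighborhood-weighted mean of the data, with the neighborhood
#' radius shrinking linearly from `radius[1]` to `radius[2]`. The codebook
#' is initialized on the plane spanned by the first two principal
#' components of the data (`init = "pca"`, the default), which makes
#' training fully deterministic and invariant to participant order; a
#' seeded random sample of data rows is available with `init = "sample"`.
#' Final quantization error never exceeds the initial-codebook quantization
#' error.
#'
#' @param ranked numeric matrix, participants x variables (typically the
#'   `ranked` element of [rank_transform_by_sex()])
#' @param grid `c(width, height)` of the unit lattice
#' @param epochs number of batch epochs
#' @param radius `c(initial, final)` Gaussian neighborhood radius in lattice
#'   units
#' @param seed integer seed (used only by the `"sample"` initialization)
#' @param init codebook initialization: `"pca"` (deterministic linear
#'   initialization on the first two principal components) or `"sample"`
#'   (seeded random data rows)
#' @return an object of class `som_model`: grid geometry, `codebook`
#'   (units x variables), training metadata and quantization errors
#' @export
train_som <- function(ranked, grid = c(8, 6), epochs = 20, radius = c(4, 1),
                      seed = 1L, init = c("pca", "sample")) {
  init <- match.arg(init)
  ranked <- as.matrix(ranked)
  g <- som_grid(grid[1], grid[2])
  n_units <- grid[1] * grid[2]
  if (n_units > 4 * nrow(ranked))
    warning("more than 4x as many map units as participants; the map will be sparse")
  codebook <- if (init == "pca") init_codebook_pca(ranked, g) else
    withr::with_seed(seed, {
      rows <- sample.int(nrow(ranked), n_units, replace = n_units > nrow(ranked))
      ranked[rows, , drop = FALSE] +
        matrix(rnorm(n_units * ncol(ranked), 0, 1e-4), n_units, ncol(ranked))
    })
  rownames(codebook) <- NULL
  qe0 <- quantization_error(codebook, ranked)
  radii <- if (epochs > 1) seq(radius[1], radius[2], length.out = epochs) else radius[2]
  for (e in seq_len(epochs)) {
    bmu <- bmu_of(codebook, ranked)
    h <- exp(-g$dist2 / (2 * radii[e]^2))  # units x units neighborhood kernel
    counts <- tabulate(bmu, nbins = n_units)
    sums <- matrix(0, n_units, ncol(ranked))
    occupied <- rowsum(ranked, bmu)
    sums[as.integer(rownames(occupied)), ] <- occupied
    num <- h %*% sums
    den <- as.vector(h %*% counts)
    codebook <- num / den  # den > 0 always: Gaussian support is global
  }
  colnames(codebook) <- colnames(ranked)
  qe1 <- quantization_error(codebook, ranked)
  structure(list(
    grid = g, codebook = codebook, variables = colnames(ranked),
    neighborhood = list(kernel = "gaussian", radius = radius),
    epochs = epochs, seed = seed,
    quantization_error = c(initial = qe0, final = qe1)
  ), class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model: ", x$grid$width, "x", x$grid$height, " grid, ",
      length(x$variables), " variables, ", x$epochs, " epochs\n", sep = "")
  cat("  quantization error: ", signif(x$quantization_error["initial"], 4),
      " -> ", signif(x$quantization_error["final"], 4), "\n", sep = "")
  invisible(x)
}

# squared Euclidean BMU over complete rows (internal fast path)
bmu_of <- function(codebook, data) {
  cross <- data %*% t(codebook)
  d2 <- outer(rowSums(data^2), rowSums(codebook^2), "+") - 2 * cross
  max.col(-d2, ties.method = "first")
}

quantization_error <- function(codebook, data) {
  bmu <- bmu_of(codebook, data)
  mean(sqrt(rowSums((data - codebook[bmu, , drop = FALSE])^2)))
}

#' Best-matching unit per participant
#'
#' Assigns every profile to the map unit with the smallest Euclidean
#' distance over its observed dimensions (missing dimensions are excluded
#' and the squared distance is normalized by the number observed). Ties go
#' to the lowest unit index; all-missing profiles get `NA` with a warning.
#'
#' @param model a `som_model`
#' @param profiles matrix with the model's variables (rank scale)
#' @return integer unit index per row of `profiles`
#' @export
assign_bmu <- function(model, profiles) {
  stopifnot(inherits(model, "som_model"))
  profiles <- as.matrix(profiles)[, model$variables, drop = FALSE]
  cb <- model$codebook
  complete <- !apply(profiles, 1, anyNA)
  out <- rep(NA_integer_, nrow(profiles))
  if (any(complete))
    out[complete] <- bmu_of(cb, profiles[complete, , drop = FALSE])
  for (i in which(!complete)) {
    obs <- !is.na(profiles[i, ])
    if (!any(obs)) {
      warning("profile ", i, " has no observed dimensions; unassigned")
      next
    }
    d2 <- colSums((t(cb[, obs, drop = FALSE]) - profiles[i, obs])^2) / sum(obs)
    out[i] <- which.min(d2)
  }
  out
}

# ---- coloring and subgroups ------------------------------------------------

#' Color the map by a trait
#'
#' Per-unit smoothed trait mean: each unit's value is the Gaussian-kernel-
#' weighted mean of the trait over the residents of the unit and its
#' lattice neighbors (`radius` in lattice units; `radius = 0` uses only the
#' unit's own residents). Units with zero smoothed weight are `NA`. As the
#' radius grows the coloring approaches the global mean everywhere.
#'
#' @param model a `som_model`
#' @param assignments BMU per participant ([assign_bmu()])
#' @param values trait value per participant
#' @param radius smoothing radius in lattice units
#' @return a `map_coloring`: `per_unit_value`, `occupancy`, `trait`
#' @export
color_map <- function(model, assignments, values, radius = 1) {
  stopifnot(inherits(model, "som_model"))
  keep <- !is.na(assignments) & !is.na(values)
  if (!any(keep)) stop_validation("no assigned participants with values")
  n_units <- nrow(model$codebook)
  sums <- tapply(as.numeric(values[keep]), factor(assignments[keep], seq_len(n_units)), sum)
  sums[is.na(sums)] <- 0
  counts <- tabulate(assignments[keep], nbins = n_units)
  h <- if (radius == 0) diag(n_units) else exp(-model$grid$dist2 / (2 * radius^2))
  wsum <- as.vector(h %*% counts)
  val <- as.vector(h %*% as.vector(sums)) / ifelse(wsum > 0, wsum, NA)
  structure(list(trait = deparse(substitute(values)),
                 per_unit_value = val, occupancy = counts, radius = radius),
            class = "map_coloring")
}

#' Partition the map into contiguous subgroups
#'
#' Default automation: seeded k-means (`K` centers, 25 restarts) on the
#' codebook vectors, followed by contiguity repair — within every k-means
#' class only the largest 4-connected lattice component keeps its label,
#' and the units of smaller fragments are reassigned to the majority label
#' among their lattice neighbors until every region is contiguous. A
#' `manual_regions` vector (one region id per unit) overrides the
#' automation, reproducing a user-drawn subgrouping. Regions are labelled
#' with roman numerals in unit-index order.
#'
#' @param model a `som_model`
#' @param K number of subgroups
#' @param manual_regions optional integer/character region per unit
#' @param assignments optional BMU per participant; when given, per-
#'   participant membership is returned too
#' @param seed seed for k-means
#' @return a `subgroup_assignment`: `regions` (region label per unit) and
#'   `membership` (per participant, if `assignments` given)
#' @export
define_subgroups <- function(model, K = 4, manual_regions = NULL,
                             assignments = NULL, seed = 1L) {
  stopifnot(inherits(model, "som_model"))
  n_units <- nrow(model$codebook)
  if (K > n_units) stop_config("K exceeds the number of map units")
  if (!is.null(manual_regions)) {
    stopifnot(length(manual_regions) == n_units)
    regions <- as.integer(factor(manual_regions,
                                 levels = unique(manual_regions)))
  } else {
    km <- withr::with_seed(seed,
      kmeans(model$codebook, centers = K, nstart = 25, iter.max = 100))
    regions <- repair_contiguity(km$cluster, model$grid)
  }
  labels <- as.roman(match(regions, unique(regions)))
  out <- list(regions = setNames(as.character(labels), seq_len(n_units)))
  if (!is.null(assignments))
    out$membership <- ifelse(is.na(assignments), NA_character_,
                             out$regions[assignments])
  structure(out, class = "subgroup_assignment")
}

# 4-neighborhood lattice adjacency
lattice_neighbors <- function(grid) {
  lapply(seq_len(nrow(grid$coords)), function(u) {
    d <- abs(grid$coords[, 1] - grid$coords[u, 1]) +
      abs(grid$coords[, 2] - grid$coords[u, 2])
    which(d == 1)
  })
}

repair_contiguity <- function(regions, grid) {
  nb <- lattice_neighbors(grid)
  components <- function(regions) {
    comp <- rep(NA_integer_, length(regions)); cid <- 0
    for (u in seq_along(regions)) {
      if (!is.na(comp[u])) next
      cid <- cid + 1
      queue <- u
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!is.na(comp[v])) next
        comp[v] <- cid
        queue <- c(queue, Filter(function(x)
          is.na(comp[x]) && regions[x] == regions[v], nb[[v]]))
      }
    }
    comp
  }
  for (iter in seq_len(length(regions))) {
    comp <- components(regions)
    sizes <- table(comp)
    fragmented <- FALSE
    for (r in unique(regions)) {
      comps_r <- unique(comp[regions == r])
      if (length(comps_r) <= 1) next
      fragmented <- TRUE
      main <- comps_r[which.max(sizes[as.character(comps_r)])]
      for (u in which(regions == r & comp != main)) {
        nb_regions <- regions[nb[[u]]]
        nb_regions <- nb_regions[nb_regions != r]
        if (length(nb_regions))
          regions[u] <- as.integer(names(which.max(table(nb_regions))))
      }
    }
    if (!fragmented) break
  }
  regions
}

# ---- bootstrap subgroup summaries ------------------------------------------

#' Bootstrap subgroup trait summaries
#'
#' For every subgroup and trait: the member mean, a percentile bootstrap
#' CI95 from `n_boot` resamples of the members with replacement, and a flag
#' marking traits whose whole-evaluation-set mean falls outside the CI95
#' (the "subgroup differs from the evaluation set" rule). Subgroups of size
#' one get a degenerate CI at the observed value and are flagged in the
#' `degenerate` column.
#'
#' @param membership subgroup label per participant (NA ignored)
#' @param traits data.frame/matrix of numeric or logical traits (rows
#'   aligned with `membership`)
#' @param n_boot bootstrap replicates (default 10,000)
#' @param seed RNG seed
#' @return data.frame: subgroup, trait, n, mean, ci_low, ci_high,
#'   eval_mean, outside_flag, degenerate
#' @export
subgroup_summary <- function(membership, traits, n_boot = 10000, seed = 1L) {
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == length(membership))
  keep <- !is.na(membership)
  membership <- membership[keep]
  traits <- traits[keep, , drop = FALSE]
  groups <- unique(membership)
  groups <- groups[order(match(groups, as.character(as.roman(1:100))),
                         groups, na.last = TRUE)]
  rows <- list()
  withr::with_seed(seed, {
    for (g in groups) {
      members <- which(membership == g)
      idx <- if (length(members) > 1)
        matrix(sample(members, n_boot * length(members), replace = TRUE),
               n_boot, length(members))
      else NULL
      for (tr in colnames(traits)) {
        x <- as.numeric(traits[[tr]])
        obs <- mean(x[members], na.rm = TRUE)
        if (is.null(idx)) {
          ci <- c(obs, obs); degen <- TRUE
        } else {
          bm <- rowMeans(matrix(x[idx], n_boot), na.rm = TRUE)
          ci <- unname(quantile(bm, c(0.025, 0.975), na.rm = TRUE))
          degen <- FALSE
        }
        ev <- mean(x, na.rm = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          subgroup = g, trait = tr, n = length(members), mean = obs,
          ci_low = ci[1], ci_high = ci[2], eval_mean = ev,
          outside_flag = ev < ci[1] | ev > ci[2], degenerate = degen,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subgroup_summary", "data.frame")
  out
}
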