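# SOM subtyping: rank normalization, batch training, BMU assignment,
# coloring, subgroup definition, and bootstrap summaries.

test_that("sex-rank normalization follows the mid-rank contract", {
  x <- cbind(v = c(3, 8, 15, 20, 41))
  rt <- rank_transform_by_sex(x, rep("female", 5))
  expect_equal(unname(rt$ranked[, "v"]), c(0, 0.25, 0.5, 0.75, 1))

  ties <- rank_transform_by_sex(cbind(v = rep(7, 6)), rep("male", 6))
  expect_equal(unname(ties$ranked[, "v"]), rep(0.5, 6))

  # disjoint raw ranges but identical within-sex orderings pool to
  # identical rank columns (the sex effect is removed)
  sex <- rep(c("female", "male"), each = 5)
  raw <- c(1, 2, 3, 4, 5, 101, 102, 103, 104, 105)
  rt2 <- rank_transform_by_sex(cbind(v = raw), sex)
  expect_equal(rt2$ranked[sex == "female", "v"],
               rt2$ranked[sex == "male", "v"], ignore_attr = TRUE)

  expect_warning(rt3 <- rank_transform_by_sex(
    cbind(v = 1:4, gone = NA_real_), rep("female", 4)), "all-missing")
  expect_false("gone" %in% colnames(rt3$ranked))
})

test_that("the evaluation transform interpolates training ranks", {
  train <- cbind(v = c(10, 20, 30, 40))
  rt <- rank_transform_by_sex(train, rep("female", 4))
  out <- apply_rank_transform(rt, cbind(v = c(10, 25, 40, 5, 99)),
                              rep("female", 5))
  expect_equal(unname(out[, "v"]), c(0, 0.5, 1, 0, 1))  # clamped at the edges
})

test_that("batch SOM training fixed points and determinism", {
  point <- matrix(0.4, 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- train_som(point, grid = c(4, 3), epochs = 5)
  expect_true(all(abs(m$codebook - 0.4) < 1e-12))

  set.seed(81)
  data <- matrix(runif(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  m1 <- train_som(data, grid = c(1, 1), epochs = 3)
  expect_equal(as.vector(m1$codebook), unname(colMeans(data)), tolerance = 1e-12)

  m2 <- train_som(data, grid = c(6, 4), epochs = 10)
  m3 <- train_som(data, grid = c(6, 4), epochs = 10)
  expect_identical(m2$codebook, m3$codebook)
  expect_lte(m2$quantization_error[["final"]], m2$quantization_error[["initial"]])
  # codebook entries stay within the training data range
  expect_true(all(m2$codebook >= min(data) & m2$codebook <= max(data)))

  # permuting participant order changes nothing (up to fp roundoff)
  perm <- sample(nrow(data))
  m4 <- train_som(data[perm, ], grid = c(6, 4), epochs = 10)
  expect_equal(m2$codebook, m4$codebook, tolerance = 1e-9)
})

test_that("well-separated clusters occupy disjoint, pure map areas", {
  set.seed(82)
  n <- 120
  cl <- rep(c(0, 1), each = n / 2)
  data <- cbind(x = 0.1 + 0.7 * cl + rnorm(n, 0, 0.03),
                y = 0.8 - 0.6 * cl + rnorm(n, 0, 0.03))
  m <- train_som(data, grid = c(6, 4), epochs = 15, radius = c(3, 1))
  bmu <- assign_bmu(m, data)
  units0 <- unique(bmu[cl == 0]); units1 <- unique(bmu[cl == 1])
  expect_length(intersect(units0, units1), 0)
  # majority label purity per occupied unit
  purity <- vapply(split(cl, bmu), function(z) max(table(z)) / length(z), 0)
  expect_gte(mean(purity >= 0.95), 0.95)
})

test_that("BMU assignment matches a brute-force scan and breaks ties low", {
  set.seed(83)
  data <- matrix(runif(120), 30, 4, dimnames = list(NULL, letters[1:4]))
  m <- train_som(data, grid = c(5, 4), epochs = 8)
  profiles <- matrix(runif(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  got <- assign_bmu(m, profiles)
  oracle <- apply(profiles, 1, function(p)
    which.min(colSums((t(m$codebook) - p)^2)))
  expect_equal(got, unname(oracle))

  # a profile equal to a codebook vector maps to that unit
  expect_equal(assign_bmu(m, m$codebook[7, , drop = FALSE]), 7L)

  # exact tie between two units resolves to the lower index
  mm <- m
  mm$codebook[] <- 50  # push every other unit far away
  mm$codebook[3, ] <- c(0, 0, 0, 1)
  mm$codebook[7, ] <- c(0, 0, 1, 0)
  tieprof <- matrix(c(0, 0, 0.5, 0.5), 1, dimnames = list(NULL, letters[1:4]))
  d3 <- sum((mm$codebook[3, ] - tieprof)^2)
  d7 <- sum((mm$codebook[7, ] - tieprof)^2)
  stopifnot(identical(d3, d7))
  expect_equal(assign_bmu(mm, tieprof), 3L)

  # missing dimensions: distance over observed dims only
  pna <- matrix(c(NA, NA, 1, 0), 1, dimnames = list(NULL, letters[1:4]))
  oracle_na <- which.min(colSums((t(m$codebook[, 3:4]) - c(1, 0))^2) / 2)
  expect_equal(assign_bmu(m, pna), unname(oracle_na))
  expect_warning(res <- assign_bmu(m, matrix(NA_real_, 1, 4,
                                             dimnames = list(NULL, letters[1:4]))),
                 "no observed dimensions")
  expect_true(is.na(res))
})

test_that("map coloring smooths towards the global mean as radius grows", {
  set.seed(84)
  data <- matrix(runif(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  m <- train_som(data, grid = c(5, 4), epochs = 8)
  bmu <- assign_bmu(m, data)
  vals <- rnorm(50)

  const <- color_map(m, bmu, rep(3.5, 50), radius = 1)
  expect_true(all(abs(const$per_unit_value - 3.5) < 1e-12))
  expect_equal(sum(const$occupancy), 50)

  solo <- color_map(m, c(7L, rep(NA, 49)), c(42, rep(NA, 49)), radius = 0)
  expect_equal(solo$per_unit_value[7], 42)
  expect_true(all(is.na(solo$per_unit_value[-7])))

  wide <- color_map(m, bmu, vals, radius = 1e6)
  expect_true(all(abs(wide$per_unit_value - mean(vals)) < 1e-6))
})

test_that("subgroup definition recovers blob partitions and respects overrides", {
  # hand-built codebook: four constant blobs in the four grid quadrants
  g <- anemiasom:::som_grid(8, 6)
  blob <- ifelse(g$coords[, 1] <= 4, 0, 1) + 2 * ifelse(g$coords[, 2] <= 3, 0, 1)
  codebook <- cbind(a = c(0, 10, 0, 10)[blob + 1], b = c(0, 0, 10, 10)[blob + 1])
  model <- structure(list(grid = g, codebook = codebook, variables = c("a", "b"),
                          neighborhood = list(kernel = "gaussian", radius = c(4, 1)),
                          epochs = 0, seed = 1,
                          quantization_error = c(initial = 0, final = 0)),
                     class = "som_model")
  sg <- define_subgroups(model, K = 4)
  expect_equal(length(unique(sg$regions)), 4)
  expect_true(all(tapply(sg$regions, blob, function(r) length(unique(r))) == 1))

  manual <- rep(c("I", "II", "III", "IV"), each = 12)
  sg2 <- define_subgroups(model, manual_regions = manual)
  expect_equal(unname(sg2$regions), manual)

  sg1 <- define_subgroups(model, K = 1)
  expect_equal(unique(sg1$regions), "I")
  expect_error(define_subgroups(model, K = 49), class = "anemiasom_config_error")

  # membership mapping follows the unit regions
  memb <- define_subgroups(model, K = 4, assignments = c(1L, 48L, NA))
  expect_equal(unname(memb$membership[1]), unname(memb$regions[1]))
  expect_true(is.na(memb$membership[3]))
})

test_that("subgroup regions are always contiguous on the lattice", {
  set.seed(85)
  data <- matrix(runif(600), 150, 4, dimnames = list(NULL, letters[1:4]))
  m <- train_som(data, grid = c(8, 6), epochs = 10)
  sg <- define_subgroups(m, K = 4)
  nb <- anemiasom:::lattice_neighbors(m$grid)
  for (r in unique(sg$regions)) {
    units <- which(sg$regions == r)
    # BFS from the first unit must reach all units of the region
    seen <- units[1]; frontier <- units[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(nb[frontier]), units), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_setequal(unname(seen), unname(units))
  }
})

test_that("evaluation never alters the trained codebook", {
  set.seed(86)
  data <- matrix(runif(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  m <- train_som(data, grid = c(5, 4), epochs = 8)
  checksum <- sum(m$codebook^2)
  invisible(assign_bmu(m, matrix(runif(400), 100, 4,
                                 dimnames = list(NULL, letters[1:4]))))
  expect_identical(sum(m$codebook^2), checksum)
})

test_that("bootstrap subgroup summaries have the right width and flags", {
  set.seed(87)
  membership <- rep(c("I", "II"), each = 100)
  traits <- data.frame(flat = rep(c(2, 5), each = 100),
                       noisy = rnorm(200))
  sm <- subgroup_summary(membership, traits, n_boot = 2000, seed = 3)
  flat_I <- sm[sm$subgroup == "I" & sm$trait == "flat", ]
  expect_equal(flat_I$mean, 2)
  expect_equal(flat_I$ci_low, 2); expect_equal(flat_I$ci_high, 2)
  expect_true(flat_I$outside_flag)  # eval mean 3.5 outside the width-0 CI

  noisy_I <- sm[sm$subgroup == "I" & sm$trait == "noisy", ]
  width <- noisy_I$ci_high - noisy_I$ci_low
  expect_lt(abs(width - 2 * 1.96 / sqrt(100)), 0.2 * 2 * 1.96 / sqrt(100))
  expect_true(noisy_I$ci_low <= noisy_I$mean && noisy_I$mean <= noisy_I$ci_high)
  # flags consistent with the CI bounds
  expect_equal(sm$outside_flag,
               sm$eval_mean < sm$ci_low | sm$eval_mean > sm$ci_high)

  # singleton subgroup: degenerate CI at the value
  one <- subgroup_summary(c("I", "II", "II"), data.frame(x = c(4, 5, 7)),
                          n_boot = 50, seed = 1)
  expect_true(one$degenerate[one$subgroup == "I"])
  expect_equal(one$ci_low[one$subgroup == "I"], 4)
})

test_that("the full pipeline produces coherent artifacts on a small cohort", {
  sc <- small_synthetic(n = 700, seed = 19)
  res <- subtype_pipeline(sc$cohort, n_boot = 200, seed = 19)
  expect_setequal(names(res$membership), res$eval_ids)
  expect_true(all(res$membership %in% c("I", "II", "III", "IV")))
  expect_equal(sort(unique(res$summary$subgroup)), sort(unique(res$membership)))
  expect_true(all(res$summary$ci_low <= res$summary$mean + 1e-12))
  expect_true(all(res$summary$mean <= res$summary$ci_high + 1e-12))
  expect_equal(length(res$subgroups$regions), 48)
  # incident-anemia incidence is defined per subgroup
  expect_true(all(res$incidence >= 0 & res$incidence <= 1, na.rm = TRUE))
})
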