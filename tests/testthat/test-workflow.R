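# Pipeline orchestration: entropy series, divergence matrices with anomaly
# flagging, and the validation of image statistics against occurrence data.

write_texture_series <- function(dir, specs, seeds, years, seasons, band = 1L) {
  paths <- character(length(seeds))
  for (i in seq_along(seeds)) {
    paths[i] <- file.path(dir, sprintf("img%02d.tif", i))
    write_raster(synth_texture(specs[[i]], seed = seeds[i]), paths[i])
  }
  data.frame(path = paths, band = band, year = years, season = seasons,
             stringsAsFactors = FALSE)
}

test_that("constant images give zero-entropy rows; clouded rows fail softly", {
  td <- tempfile(); dir.create(td)
  paths <- character(3)
  for (i in 1:3) {
    paths[i] <- file.path(td, sprintf("c%d.tif", i))
    write_raster(matrix(100L + i, 160, 160), paths[i])
  }
  # one fully masked image (every pixel at the nodata value)
  bad <- file.path(td, "bad.tif")
  write_raster(matrix(0L, 160, 160), bad, nodata = 0)
  man <- data.frame(path = c(paths, bad), band = 1L,
                    year = c(2001, 2001, 2002, 2002),
                    season = c("dry", "wet", "dry", "wet"))
  es <- run_entropy_series(man, min_side = 128, stride = 32, out_dir = td)
  ok <- es[es$status == "ok", ]
  expect_equal(nrow(ok), 3L)
  expect_true(all(ok$entropy == 0))
  expect_equal(sum(es$status != "ok"), 1L)
  expect_true(file.exists(file.path(td, "entropy_series.csv")))
  expect_true(file.exists(file.path(td, "run_log.json")))
})

test_that("textures spreading intensity over more of the DN range have higher entropy", {
  # after min-max quantization the DN spread is governed by the subband
  # shape: heavy tails compress the bulk into few bins
  td <- tempfile(); dir.create(td)
  heavy <- texture_spec(c(256, 256), "d4", 3, subband_params_for(0.7))
  light <- texture_spec(c(256, 256), "d4", 3, subband_params_for(2))
  man <- write_texture_series(td, list(heavy, light), c(1, 1),
                              c(2001, 2001), c("dry", "wet"))
  es <- run_entropy_series(man, min_side = 128, stride = 64)
  expect_lt(es$entropy[es$season == "dry"], es$entropy[es$season == "wet"])
})

test_that("identical images give a zero matrix; outputs are symmetric files", {
  td <- tempfile(); dir.create(td)
  spec <- texture_spec(c(256, 256), "d4", 3, subband_params_for(1.5))
  man <- write_texture_series(td, rep(list(spec), 4), rep(7, 4),
                              c(2001, 2001, 2002, 2002),
                              c("dry", "wet", "dry", "wet"))
  res <- run_divergence_matrix(man, min_side = 128, stride = 64, out_dir = td)
  m <- res$per_band[["1"]]
  expect_true(all(m == 0))
  expect_equal(rownames(m), c("2001-dry", "2001-wet", "2002-dry", "2002-wet"))
  back <- read_divergence_csv(file.path(td, "divergence_band1.csv"))
  expect_equal(unclass(back), t(unclass(back)))
})

test_that("the across-band matrix dominates each per-band matrix elementwise", {
  td <- tempfile(); dir.create(td)
  spec1 <- texture_spec(c(128, 128), "d4", 2, subband_params_for(1.3)[1:6])
  spec2 <- texture_spec(c(128, 128), "d4", 2, subband_params_for(1.9)[1:6])
  seq1 <- list(spec1, spec1, spec2)   # band 1 changes at period 3
  seq2 <- list(spec2, spec1, spec1)   # band 2 changes at period 2
  paths <- character(3)
  for (i in 1:3) {
    arr <- array(0L, c(128, 128, 3))
    arr[, , 1] <- synth_texture(seq1[[i]], seed = i)
    arr[, , 2] <- synth_texture(seq2[[i]], seed = 10 + i)
    arr[, , 3] <- 128L
    paths[i] <- file.path(td, sprintf("multi%d.tif", i))
    write_raster(arr, paths[i])
  }
  man <- data.frame(path = rep(paths, 2), band = rep(1:2, each = 3),
                    year = rep(2001:2003, 2), season = "dry",
                    stringsAsFactors = FALSE)
  res <- run_divergence_matrix(man, levels = 2L, min_side = 64, stride = 64)
  expect_length(res$per_band, 2L)
  expect_false(is.null(res$max_matrix))
  for (b in names(res$per_band)) {
    expect_true(all(res$max_matrix >= res$per_band[[b]] - 1e-12))
  }
})

test_that("rerunning with the same inputs reproduces byte-identical CSVs", {
  td1 <- tempfile(); td2 <- tempfile()
  src <- tempfile(); dir.create(src)
  spec <- texture_spec(c(128, 128), "d4", 2, subband_params_for(1.5)[1:6])
  man <- write_texture_series(src, rep(list(spec), 3), 1:3,
                              c(2001, 2002, 2003), "dry")
  for (out in c(td1, td2)) {
    run_entropy_series(man, min_side = 64, stride = 32, out_dir = out)
    run_divergence_matrix(man, levels = 2L, min_side = 64, stride = 32, out_dir = out)
  }
  for (f in c("entropy_series.csv", "divergence_band1.csv")) {
    expect_identical(readLines(file.path(td1, f)), readLines(file.path(td2, f)))
  }
})

# deterministic communities: period i+1 replaces the first n_repl[i] species
chained_communities <- function(n_repl, richness = 30) {
  comm <- list(sprintf("sp%03d", seq_len(richness)))
  next_id <- richness
  for (r in n_repl) {
    prev <- comm[[length(comm)]]
    fresh <- sprintf("sp%03d", next_id + seq_len(r))
    next_id <- next_id + r
    comm[[length(comm) + 1]] <- c(prev[setdiff(seq_len(richness), seq_len(r))], fresh)
  }
  comm
}

grid_of_community <- function(sp, label) {
  grid_occurrences(
    data.frame(species = sp, x = 15, y = 15, date = "2001-01-15"),
    resolution = 30, origin = c(0, 0), dim = c(1, 1), period = label)
}

test_that("a constructed divergence-turnover proportionality is recovered", {
  n_repl <- c(0, 3, 6, 9, 12)
  comm <- chained_communities(n_repl)
  betas <- n_repl * 2 / (30 + n_repl)        # exact per-pair Jaccard distance
  # subband scales drift (level 1 up, level 2 down) by steps solved so that
  # the model divergence between consecutive standardized windows equals
  # 3 * beta exactly; fitting then has to recover the proportionality
  drift <- drifted_texture_series(betas, amp = 3)
  labels <- sprintf("p%d", seq_along(comm))
  sigs <- list(); H <- numeric(length(comm))
  for (i in seq_along(comm)) {
    img <- synth_texture(texture_spec(c(512, 512), "d4", 2, drift$params[[i]],
                                      quantization = 0), seed = 400 + i)
    z <- (img - mean(img)) / sd(img)
    sigs[[i]] <- fit_signature(z, "d4", 2)
    H[i] <- intensity_entropy(z)
  }
  names(sigs) <- labels
  grids <- setNames(lapply(seq_along(comm), function(i)
    grid_of_community(comm[[i]], labels[i])), labels)
  rep <- run_validation(setNames(H, labels), sigs, grids, n_boot = 200, seed = 5)
  expect_gt(rep$beta_vs_kl$r_squared, 0.9)
  expect_equal(rep$pairs$beta, betas, tolerance = 1e-12)
  # shuffling the pairing of images and communities degrades the fit
  shuffled <- grids[c(4, 6, 1, 5, 2, 3)]
  names(shuffled) <- labels
  rep2 <- run_validation(setNames(H, labels), sigs, shuffled, n_boot = 200, seed = 5)
  expect_lt(rep2$beta_vs_kl$r_squared, rep$beta_vs_kl$r_squared)
})

test_that("a no-change series yields near-zero turnover and predictors", {
  comm <- chained_communities(c(0, 0, 0))
  labels <- sprintf("p%d", 1:4)
  spec <- texture_spec(c(256, 256), "d4", 2, subband_params_for(1.5)[1:6])
  imgs <- lapply(1:4, function(i) synth_texture(spec, seed = 200 + i))
  sigs <- setNames(lapply(imgs, fit_signature, wavelet = "d4", levels = 2), labels)
  H <- setNames(vapply(imgs, intensity_entropy, numeric(1)), labels)
  grids <- setNames(lapply(1:4, function(i) grid_of_community(comm[[i]], labels[i])),
                    labels)
  expect_error(run_validation(H, sigs, grids[1:3]), class = "texdiv_domain_error")
  rep <- run_validation(H, sigs, grids, n_boot = 50, seed = 2)
  expect_true(all(rep$pairs$beta == 0))
  # only estimation noise, far below a meaningful class separation (~1 nat)
  expect_true(all(rep$pairs$kl < 0.3))
  expect_true(all(rep$pairs$dH < 0.2))
})
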