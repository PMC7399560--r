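# oxDNA readers/writers and the internal ensemble container

toy_oxdna_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  # 12-nucleotide duplex (two 6-nt strands), two frames
  top <- c("12 2",
           paste(1, "A", c(-1, 0:4), c(1:5, -1)),
           paste(2, "T", c(-1, 6:10), c(7:11, -1)))
  topf <- file.path(dir, "toy.top")
  writeLines(top, topf)
  conf <- character(0)
  for (fr in 0:1) {
    rows <- sapply(0:11, function(i) {
      strand <- if (i < 6) 0 else 1
      z <- if (strand == 0) i else 11 - i
      x <- if (strand == 0) 1 else -1
      paste(x + fr, 0, z, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0)
    })
    conf <- c(conf, paste("t =", fr), "b = 100 100 100", "E = 0 0 0", rows)
  }
  conff <- file.path(dir, "toy.dat")
  writeLines(conf, conff)
  list(top = topf, conf = conff)
}

test_that("a toy two-frame duplex trajectory reads with correct frame count and units", {
  f <- toy_oxdna_files()
  ens <- read_oxdna(f$top, f$conf)
  expect_s3_class(ens, "conformation_ensemble")
  expect_equal(ens$count, 2L)
  cf <- ens$conformations[[1]]
  expect_equal(nrow(cf$positions), 12L)
  # length-unit conversion applied exactly once: oxDNA x = 1 -> 0.8518 nm
  expect_equal(cf$positions[1, 1], OXDNA_LENGTH_NM, tolerance = 1e-12)
  # complementarity pairing: both strands span the same bp planes
  expect_equal(sort(unique(cf$bp_index)), 0:5)
  expect_true(all(table(cf$bp_index) == 2))
})

test_that("oxDNA write/read round trip preserves positions and indexing", {
  dir <- withr::local_tempdir()
  rod <- make_straight_rod(contour_length = 10.2, n_points = 30L)
  ens <- conformation_ensemble(list(rod), provenance = list(seed = 1234L))
  topf <- file.path(dir, "rt.top"); conff <- file.path(dir, "rt.dat")
  mapf <- file.path(dir, "rt.map.tsv")
  write_oxdna(ens, topf, conff, duplex_map_path = mapf)
  back <- read_oxdna(topf, conff, duplex_map = mapf,
                     contour_length = 10.2)
  expect_equal(back$count, 1L)
  cf0 <- ens$conformations[[1]]; cf1 <- back$conformations[[1]]
  ord0 <- order(cf0$duplex_id, cf0$strand_id, cf0$bp_index)
  ord1 <- order(cf1$duplex_id, cf1$strand_id, cf1$bp_index)
  expect_lt(max(abs(cf0$positions[ord0, ] - cf1$positions[ord1, ])), 1e-9)
  expect_equal(cf0$duplex_id[ord0], cf1$duplex_id[ord1])
  expect_equal(cf0$bp_index[ord0], cf1$bp_index[ord1])
})

test_that("malformed oxDNA inputs raise parse errors naming the problem", {
  f <- toy_oxdna_files()
  # frame with one nucleotide row removed -> count mismatch
  lines <- readLines(f$conf)
  writeLines(lines[-5], f$conf)
  expect_error(read_oxdna(f$top, f$conf), "count mismatch")
  # malformed topology header
  f2 <- toy_oxdna_files()
  top <- readLines(f2$top)
  writeLines(c("garbage header", top[-1]), f2$top)
  expect_error(read_oxdna(f2$top, f2$conf), "line 1")
  # >2 strands without a duplex map is ambiguous
  f3 <- toy_oxdna_files()
  top <- readLines(f3$top)
  top[1] <- "12 3"
  top[8] <- sub("^2", "3", top[8])
  writeLines(top, f3$top)
  expect_error(read_oxdna(f3$top, f3$conf), "duplex_map required")
})

test_that("the internal container round-trips losslessly and checks its version", {
  dir <- withr::local_tempdir()
  ens <- fx_achiral_ensemble()
  small <- conformation_ensemble(ens$conformations[1:2],
                                 provenance = list(seed = 1234L, note = "rt"))
  path <- file.path(dir, "ens.rds")
  write_ensemble(small, path)
  back <- read_ensemble(path)
  expect_identical(back$provenance$seed, 1234L)
  expect_identical(back$conformations[[1]]$positions,
                   small$conformations[[1]]$positions)
  expect_identical(back$count, small$count)
  # empty file is an error, not an empty ensemble
  empty <- file.path(dir, "empty.rds")
  file.create(empty)
  expect_error(read_ensemble(empty), "empty")
  # version mismatch is flagged with the stored version
  bad <- file.path(dir, "bad.rds")
  saveRDS(list(format = "origamiLC_ensemble", version = 99L,
               ensemble = small), bad)
  expect_error(read_ensemble(bad), "version")
})

test_that("conformation validators enforce the indexing invariants", {
  rod <- make_straight_rod(contour_length = 10.2, n_points = 30L)
  expect_silent(validate_conformation(rod))
  bad <- rod
  bad$bp_index[2] <- bad$bp_index[1]
  bad$strand_id[2] <- bad$strand_id[1]
  bad$duplex_id[2] <- bad$duplex_id[1]
  expect_error(validate_conformation(bad), "unique")
  bad2 <- rod
  bad2$base_vectors[1, ] <- c(2, 0, 0)
  expect_error(validate_conformation(bad2), "unit norm")
})
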