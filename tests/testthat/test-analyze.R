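make_fixture_set <- function(preset = "substrate", n_reps = 2,
                             n_frames = 300, seed_base = 40) {
  root <- tempfile("runs")
  reps <- lapply(seq_len(n_reps), function(r) {
    d <- file.path(root, sprintf("rep%d", r))
    generate_fixture(preset, n_frames, seed_base + r, d,
                     replicate_id = sprintf("rep%d", r))
    list(topology = file.path(d, "topology.pdb"),
         frames = file.path(d, "frames.dcd"),
         id = sprintf("rep%d", r))
  })
  list(root = root, reps = reps)
}

test_that("YAML configs are validated with actionable messages", {
  fx <- make_fixture_set(n_reps = 1)
  cfgfile <- tempfile(fileext = ".yaml")
  writeLines(sprintf(
    "replicates:\n  - topology: %s\n    frames: %s\n    id: rep1\noutput_dir: %s\nhbond_max_distance: 2.5\n",
    fx$reps[[1]]$topology, fx$reps[[1]]$frames,
    file.path(fx$root, "out")), cfgfile)
  cfg <- run_config(cfgfile)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$hbond_max_distance, 2.5)

  writeLines("bogus_key: 1\n", cfgfile)
  expect_error(run_config(cfgfile), "unknown config key")
  writeLines("replicates:\n  - topology: /nonexistent\n    frames: /nope\n",
             cfgfile)
  expect_error(run_config(cfgfile), "not found")
  expect_error(run_config(tempfile()), "not found")
})

test_that("the full analysis run produces a coherent report bundle", {
  fx <- make_fixture_set(n_reps = 2, n_frames = 400)
  cfg <- default_config(fx$reps, file.path(fx$root, "out"))
  cfg$pocket$enabled <- TRUE
  cfg$pocket$grid_spacing <- 1.0
  res <- analyze_run(cfg)

  expect_s3_class(res$landscape, "fes")
  expect_equal(res$landscape$histogram$total, 800L)
  expect_equal(sum(res$levels$percent), 100, tolerance = 1e-6)
  expect_true(all(file.exists(unlist(res$files))))
  expect_equal(nrow(res$volumes), 800)

  # every CSV carries the config hash header
  for (f in unlist(res$files)) {
    first <- readLines(f, n = 1)
    expect_match(first, "config_hash=")
  }

  # landscape CSV re-reads into the same dG values
  tab <- read.csv(res$files$landscape_pooled, comment.char = "#")
  expect_equal(sort(unique(tab$dG_kT[tab$count > 0])),
               sort(unique(as.vector(
                 res$landscape$dG[res$landscape$histogram$counts > 0]))),
               tolerance = 1e-9)
})

test_that("identical config and inputs give identical report bytes", {
  fx <- make_fixture_set(n_reps = 1, n_frames = 200)
  out1 <- file.path(fx$root, "o1"); out2 <- file.path(fx$root, "o2")
  r1 <- analyze_run(default_config(fx$reps, out1))
  r2 <- analyze_run(default_config(fx$reps, out2))
  for (nm in names(r1$files)) {
    b1 <- readBin(r1$files[[nm]], "raw", file.size(r1$files[[nm]]))
    f2 <- file.path(out2, basename(r1$files[[nm]]))
    b2 <- readBin(f2, "raw", file.size(f2))
    expect_identical(b1, b2)
  }
  # fixture generation itself is byte-deterministic given the seed
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture("substrate", 100, 7, d1)
  generate_fixture("substrate", 100, 7, d2)
  expect_identical(readLines(file.path(d1, "labels.csv")),
                   readLines(file.path(d2, "labels.csv")))
})

test_that("single-frame inputs and missing atoms degrade cleanly", {
  fx <- make_fixture_set(n_reps = 1, n_frames = 1)
  cfg <- default_config(fx$reps, file.path(fx$root, "out1f"))
  res <- analyze_run(cfg)
  expect_equal(res$landscape$histogram$total, 1L)
  expect_true(file.exists(res$files$conditional))

  # config pointing at a topology without the triad fails before pooling
  bad_dir <- tempfile()
  dir.create(bad_dir)
  t1 <- trajectory(tiny_topology(4), array(rnorm(4 * 3 * 5), c(4, 3, 5)))
  write_trajectory(t1, file.path(bad_dir, "topology.pdb"),
                   file.path(bad_dir, "frames.dcd"))
  cfg_bad <- default_config(list(list(
    topology = file.path(bad_dir, "topology.pdb"),
    frames = file.path(bad_dir, "frames.dcd"), id = "bad")),
    file.path(bad_dir, "out"))
  expect_warning(expect_error(analyze_run(cfg_bad), "all replicates failed"),
                 "no atom matches")
})

test_that("pooled analysis of substrate replicates recovers the kinked
           basin", {
  fx <- make_fixture_set("substrate", n_reps = 5, n_frames = 2000,
                         seed_base = 60)
  cfg <- default_config(fx$reps, file.path(fx$root, "out"))
  res <- analyze_run(cfg)
  m <- res$minimum
  expect_lte(abs(m$x - 2.0), 0.1)
  expect_lte(abs(m$y - 2.2), 0.1)
})
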