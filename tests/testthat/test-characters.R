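test_that("completion applies the four lateral-medial scoring rules", {
  ## columella absent pulls everything lateral to absent
  t1 <- complete_triple(structure_triple("a", "?", "?", "absent"))
  expect_equal(c(t1$tm, t1$ta, t1$co), c("absent", "absent", "absent"))
  ## membrane present pulls everything medial to present
  t2 <- complete_triple(structure_triple("b", "present", "?", "?"))
  expect_equal(c(t2$tm, t2$ta, t2$co), c("present", "present", "present"))
  ## annulus absent silences the membrane but says nothing about the
  ## columella (a columella can occur without an annulus)
  t3 <- complete_triple(structure_triple("c", "?", "absent", "?"))
  expect_equal(c(t3$tm, t3$ta, t3$co), c("absent", "absent", "unknown"))
  ## membrane present with columella absent is contradictory
  expect_error(complete_triple(structure_triple("d", "present", "?", "absent")),
               "assumption")
  expect_error(complete_triple(structure_triple("e", "?", "present", "absent")),
               "assumption")
})

test_that("completion is idempotent and monotone over the whole state space", {
  states <- c("present", "absent", "unknown")
  grid <- expand.grid(tm = states, ta = states, co = states,
                      stringsAsFactors = FALSE)
  n_ok <- 0L
  for (i in seq_len(nrow(grid))) {
    raw <- structure_triple("x", grid$tm[i], grid$ta[i], grid$co[i])
    done <- tryCatch(complete_triple(raw), error = function(e) NULL)
    if (is.null(done)) next
    n_ok <- n_ok + 1L
    ## idempotent
    again <- complete_triple(done)
    expect_identical(unclass(again), unclass(done))
    ## monotone: known fields never flipped, only unknowns filled
    for (f in c("tm", "ta", "co"))
      if (raw[[f]] != "unknown") expect_identical(done[[f]], raw[[f]])
    ## completed rows with no unknowns respect the presence ordering
    st <- c(done$tm, done$ta, done$co)
    expect_false(st[1] == "present" && st[2] == "absent")
    expect_false(st[2] == "present" && st[3] == "absent")
  }
  expect_gt(n_ok, 10)  # most of the 27 combinations are consistent
})

test_that("character tables are read, completed, and audited", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tTM\tTA\tCO",
               "Bufo_bufo\t1\t1\t1",
               "Osornophryne_guacamayo\t0\t0\t0",
               "Atelopus_ignescens\t?\t0\t?",
               "Broken_taxon\t1\t?\t0"), path)
  m <- read_character_table(path)
  expect_s3_class(m, "character_matrix")
  expect_equal(nrow(m), 3L)  # inconsistent row excluded
  bad <- attr(m, "inconsistent")
  expect_equal(bad$taxon, "Broken_taxon")
  expect_equal(bad$line, 5L)
  expect_true("Atelopus_ignescens" %in% attr(m, "altered"))
  ## completion filled TM from TA-absent, left CO unknown
  expect_equal(m$tm[m$taxon == "Atelopus_ignescens"], "absent")
  expect_equal(m$co[m$taxon == "Atelopus_ignescens"], "unknown")

  co <- extract_binary(m, "CO")
  expect_identical(co[["Bufo_bufo"]], 1L)
  expect_identical(co[["Osornophryne_guacamayo"]], 0L)
  expect_true(is.na(co[["Atelopus_ignescens"]]))
  tm <- extract_binary(m, "TM")
  expect_identical(tm[["Osornophryne_guacamayo"]], 0L)

  ## errors name line numbers
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tTM\tTA\tCO", "A\t1\t1\t1", "A\t0\t0\t0"), path2)
  expect_error(read_character_table(path2), "duplicate taxon at line")
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tTM\tTA\tCO", "A\tmaybe\t1\t1"), path3)
  expect_error(read_character_table(path3), "line\\(s\\) 2")
  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("taxon\tTM\tTA\tCO", path4)
  expect_error(read_character_table(path4), "empty")
  expect_error(read_character_table("no/such/file.tsv"), "no/such/file.tsv")
})

test_that("completed matrices respect the presence ordering invariant", {
  phy <- yule_tree(60, 1, seed = 11)
  dep <- simulate_dependent_triple(phy, rate_matrix(0.2, 0.6),
                                   rate_matrix(0.5, 0.5), seed = 12)
  m <- dep$matrix
  expect_lte(sum(m$tm == "present"), sum(m$ta == "present"))
  expect_lte(sum(m$ta == "present"), sum(m$co == "present"))
})
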