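test_that("gesture table parsing assigns ordinals and error flags", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\tGN\t0\t1", "1\tDN\t0\t1", "1\tRN\t1\t1"), p)
  g <- read_gesture_table(p)
  expect_equal(nrow(g), 3)
  expect_equal(g$ordinal, 0:2)
  expect_equal(sum(g$error), 1)
  expect_true(g$error[3])

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_equal(nrow(read_gesture_table(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("1\tGN\t2\t1", bad)
  expect_error(read_gesture_table(bad), "error flag")
  writeLines("1\tXX\t0\t1", bad)
  expect_error(read_gesture_table(bad), "unknown gesture")
  expect_equal(read_gesture_table(bad, strict = FALSE)$label, "XX")
})

test_that("maneuver table parsing collapses raw labels and splits trials", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\tST\t0", "1\tGPR\t0", "1\tTLK_L\t1"), p)
  m <- read_maneuver_table(p)
  expect_equal(m$label_collapsed, c("ST", "GPR", "TLK"))
  expect_equal(m$incomplete, c(FALSE, FALSE, TRUE))

  writeLines(c("1\tST\t0", "2\tST\t0", "1\tGPR\t0", "2\tIMS\t0"), p)
  m2 <- read_maneuver_table(p)
  expect_equal(m2$ordinal[m2$trial_id == 1], 0:1)
  expect_equal(m2$ordinal[m2$trial_id == 2], 0:1)

  writeLines("1\tNOPE\t0", p)
  expect_error(read_maneuver_table(p), "unknown maneuver")
})

test_that("skill table parsing validates classes, duplicates and items", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1\t1\t24", "2\t0\t12"), p)
  s <- read_skill_table(p)
  expect_equal(s$experience_class, c(1L, 0L))
  expect_equal(s$grs_total, c(24L, 12L))

  writeLines(c("1\t1\t24", "1\t0\t12"), p)
  expect_error(read_skill_table(p), "duplicated trial")
  writeLines("1\t2\t24", p)
  expect_error(read_skill_table(p), "experience class")
  writeLines("1\t1\t25\t4\t4\t4\t4\t4\t4", p)
  expect_error(read_skill_table(p), "sum of item scores")
  writeLines("1\t1\t24\t4\t4\t4\t4\t4\t4", p)
  expect_equal(read_skill_table(p)$grs3, 4L)
})

test_that("tables round-trip through write and read field for field", {
  d <- withr::local_tempdir()
  gen <- generate_dataset(n_expert_surgeons = 1, n_novice_surgeons = 2,
                          trials_per_surgeon = 2, seed = 5)
  simulate_to_dir(d, seed = 5, n_expert_surgeons = 1, n_novice_surgeons = 2,
                  trials_per_surgeon = 2)
  g <- read_gesture_table(file.path(d, "gestures.txt"))
  m <- read_maneuver_table(file.path(d, "maneuvers.txt"))
  s <- read_skill_table(file.path(d, "skills.txt"))
  d2 <- withr::local_tempdir()
  write_gesture_table(g, file.path(d2, "g.txt"))
  write_maneuver_table(m, file.path(d2, "m.txt"))
  write_skill_table(s, file.path(d2, "s.txt"))
  expect_identical(read_gesture_table(file.path(d2, "g.txt")), g)
  expect_identical(read_maneuver_table(file.path(d2, "m.txt")), m)
  expect_identical(read_skill_table(file.path(d2, "s.txt")), s)
})

test_that("assembly cross-references records and reports violations", {
  d <- withr::local_tempdir()
  tp <- write_toy_tables(
    d,
    gestures = c("1\tGN\t0\t1", "1\tDN\t0\t1", "2\tLS\t0\t3"),
    maneuvers = c("1\tST\t0", "1\tGPR\t0", "2\tTLK_L\t0"),
    skills = c("1\t1\t24", "2\t0\t12", "3\t0\t10")
  )
  ds <- assemble_dataset(read_gesture_table(tp$gestures),
                         read_maneuver_table(tp$maneuvers),
                         read_skill_table(tp$skills))
  expect_equal(length(trials(ds)), 3)
  expect_equal(sum(ds$validation$severity == "error"), 0)
  # trial 3 exists only in the skill table: retained, flagged as warning
  expect_equal(nrow(trials(ds)[["3"]]$maneuvers), 0)
  expect_true(any(ds$validation$trial_id == 3 &
                    ds$validation$severity == "warning"))

  # reference past the maneuver table ends up in the validation report
  bad <- assemble_dataset(
    read_gesture_table({
      f <- withr::local_tempfile(); writeLines("1\tGN\t0\t9", f); f
    }),
    read_maneuver_table(tp$maneuvers),
    read_skill_table(tp$skills))
  expect_true(any(grepl("out of range", bad$validation$problem)))

  # reference into another trial's maneuver rows is also an error
  cross <- assemble_dataset(
    read_gesture_table({
      f <- withr::local_tempfile(); writeLines("1\tGN\t0\t3", f); f
    }),
    read_maneuver_table(tp$maneuvers),
    read_skill_table(tp$skills))
  expect_true(any(grepl("in trial 2", cross$validation$problem)))

  # activity without a skill record is an error
  orphan <- assemble_dataset(read_gesture_table(tp$gestures),
                             read_maneuver_table(tp$maneuvers),
                             read_skill_table({
                               f <- withr::local_tempfile()
                               writeLines("1\t1\t24", f); f
                             }))
  expect_true(any(grepl("no skill record", orphan$validation$problem)))
})

test_that("maneuver and gesture sequence extraction respects order and level", {
  tr <- make_toy_trial(1, c("ST", "GPR", "TLK_L"),
                       list(c("GN", "DN"), c("GN", "PN"),
                            c("LS", "GT", "PT", "TK")))
  expect_equal(maneuver_sequence(tr), c("ST", "GPR", "TLK"))
  expect_equal(maneuver_sequence(tr, collapsed = FALSE),
               c("ST", "GPR", "TLK_L"))
  expect_equal(gesture_sequence_within(tr, "TLK"),
               list(c("LS", "GT", "PT", "TK")))
  expect_equal(gesture_sequence_within(tr, "OLK"), list())

  two <- make_toy_trial(2, c("OLK_L", "IMS", "OLK_R"),
                        list(c("LS", "TK"), "AD", c("GT", "PT")))
  expect_equal(gesture_sequence_within(two, "OLK"),
               list(c("LS", "TK"), c("GT", "PT")))

  empty <- surg_trial(3, make_toy_trial(1, "ST", list("GN"))$maneuvers[0, ],
                      make_toy_trial(1, "ST", list("GN"))$gestures[0, ])
  expect_equal(maneuver_sequence(empty), character(0))
})

test_that("gesture sequences within maneuvers partition the full sequence", {
  gen <- generate_dataset(n_expert_surgeons = 2, n_novice_surgeons = 2,
                          trials_per_surgeon = 3, seed = 11)
  for (tr in trials(gen$dataset)) {
    expect_equal(length(maneuver_sequence(tr)), nrow(tr$maneuvers))
    rebuilt <- character(0)
    mseq <- maneuver_sequence(tr)
    inst_seen <- stats::setNames(rep(0L, 5), c("ST", "GPR", "TLK", "OLK", "IMS"))
    for (M in mseq) {
      inst_seen[M] <- inst_seen[M] + 1L
      rebuilt <- c(rebuilt, gesture_sequence_within(tr, M)[[inst_seen[M]]])
    }
    expect_equal(rebuilt, tr$gestures$label)
  }
})

test_that("frame tracks round-trip in both layouts", {
  labels <- c(".bg", "GN", "GN", "DN", ".bg", "PT")
  tr <- frame_track(labels, "ann1", "either")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_frame_track(tr, f1, "frames")
  write_frame_track(tr, f2, "rle")
  expect_equal(read_frame_track(f1, "ann1", "either", n_frames = 6)$labels,
               labels)
  expect_equal(read_frame_track(f2, "ann1", "either", n_frames = 6)$labels,
               labels)
  expect_error(read_frame_track(f2, "x", "either"), "n_frames")
})

test_that("vocabulary configuration round-trips through YAML", {
  v <- default_vocabulary()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_vocabulary(v, f)
  v2 <- read_vocabulary(f)
  expect_identical(v2$collapse_map, v$collapse_map)
  expect_identical(v2$gestures, v$gestures)
  expect_setequal(v$maneuvers_collapsed, c("ST", "GPR", "TLK", "OLK", "IMS"))
  expect_equal(nrow(v$gestures), 30)
})
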