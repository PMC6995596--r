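test_that("load_crosslinks reads well-formed rows and collects bad ones", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("protein_1,residue_1,protein_2,residue_2,linker",
               "FXIII-A,600,FXIII-B,30,DSS",
               "FXIII-A,0,FXIII-B,12,DSS",
               "FXIII-B,45,FXIII-B,101,DSS",
               "FXIII-A,150,FXIII-B,400,DSS"), f)
  xls <- load_crosslinks(f)
  expect_equal(nrow(xls), 3L)
  expect_equal(attr(xls, "errors")$row, 2L)
  expect_equal(xls$kind, c("inter", "intra", "inter"))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("protein_1,residue_1,protein_2,residue_2,linker",
               "A,0,B,0,DSS"), bad)
  expect_error(load_crosslinks(bad), "no parseable")
})

test_that("cross-link CSV round trip preserves every field", {
  m <- toy_model(2, 25, seed = 1)
  xls <- sample_crosslinks(m, n = 12, satisfied_fraction = 0.5, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_crosslinks(xls, f)
  back <- load_crosslinks(f)
  expect_equal(as.data.frame(back), as.data.frame(xls),
               ignore_attr = TRUE)
})

test_that("build_restraints applies the 3-24 A DSS window and expands ambiguity", {
  xls <- crosslink_set("A2", 100, "B", 30)
  rs <- build_restraints(xls, list(A2 = "A", B = "B"))
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$lower, 3)
  expect_equal(rs$upper, 24)
  # two candidate chains on each side: 4 restraints under one parent
  rs4 <- build_restraints(xls, list(A2 = c("A", "C"), B = c("B", "D")))
  expect_equal(nrow(rs4), 4L)
  expect_equal(unique(rs4$group), 1)
  expect_equal(nrow(unique(rs4[c("chain_1", "chain_2")])), 4L)
  # empty input, empty output
  empty <- crosslink_set(character(0), integer(0), character(0), integer(0))
  expect_equal(nrow(build_restraints(empty, list())), 0L)
  expect_error(build_restraints(xls, list(A2 = "A")), "no chain assignment")
})

test_that("evaluate_restraints measures anchor distances and statuses", {
  # two CB atoms 10 A apart: satisfied; 30 A apart: violated with excess 6
  at <- data.frame(
    chain = c("A", "A", "B", "B", "B", "B"),
    resno = c(1, 1, 1, 1, 2, 2),
    resid = "ALA",
    elety = c("CA", "CB", "CA", "CB", "CA", "CB"),
    x = c(0, 0, 10.2, 10, 30.5, 30), y = 0, z = 0)
  m <- atomic_model(at)
  xls <- crosslink_set(c("P", "P"), c(1, 1), c("Q", "Q"), c(1, 2))
  rs <- build_restraints(xls, list(P = "A", Q = "B"))
  rep <- evaluate_restraints(m, rs)
  expect_equal(rep$per_restraint$distance, c(10, 30))
  expect_equal(rep$per_restraint$status, c("satisfied", "violated"))
  expect_equal(rep$per_restraint$excess, c(0, 6))
  expect_equal(rep$n_total, 2L)
  expect_equal(rep$satisfaction_fraction, 0.5)
})

test_that("planted cross-link sets reproduce their construction fraction", {
  m <- toy_model(2, 25, seed = 1)
  for (frac in c(0, 0.75, 1)) {
    xls <- sample_crosslinks(m, n = 40, satisfied_fraction = frac, seed = 7)
    rs <- build_restraints(xls, list(A = "A", B = "B"))
    rep <- evaluate_restraints(m, rs)
    expect_equal(rep$satisfaction_fraction, frac)
  }
})

test_that("restraint evaluation agrees with brute-force distances and is
           invariant to selector swap and rigid transforms", {
  m <- toy_model(2, 25, seed = 2)  # < 500 atoms
  xls <- sample_crosslinks(m, n = 30, satisfied_fraction = 0.6, seed = 9)
  rs <- build_restraints(xls, list(A = "A", B = "B"))
  rep <- evaluate_restraints(m, rs)
  # brute-force all-pairs oracle
  for (i in seq_len(nrow(rs))) {
    expect_equal(rep$per_restraint$distance[i],
                 brute_anchor_distance(m, rs$chain_1[i], rs$resno_1[i],
                                       rs$chain_2[i], rs$resno_2[i]),
                 tolerance = 1e-12)
  }
  # swapping selectors never changes status
  swapped <- rs
  swapped[c("chain_1", "resno_1", "chain_2", "resno_2")] <-
    rs[c("chain_2", "resno_2", "chain_1", "resno_1")]
  attr(swapped, "anchor") <- attr(rs, "anchor")
  expect_equal(evaluate_restraints(m, swapped)$per_group$status,
               rep$per_group$status)
  # satisfaction invariant under rigid motion of the whole model
  moved <- apply_transform(m, rot_z(123, c(15, -40, 7)))
  expect_equal(evaluate_restraints(moved, rs)$satisfaction_fraction,
               rep$satisfaction_fraction)
})

test_that("unmappable residues are excluded from the fraction", {
  m <- toy_model(1, 10, seed = 1)
  xls <- crosslink_set(c("A", "A"), c(1, 2), c("A", "A"), c(5, 999))
  rs <- build_restraints(xls, list(A = "A"))
  rep <- evaluate_restraints(m, rs)
  expect_equal(rep$n_unmappable, 1L)
  expect_equal(rep$n_total, 1L)
})

test_that("domain contact matrix buckets by domain pair and sums to n", {
  a_dom <- fxiii_a_domains()
  b_dom <- domain_map(data.frame(
    domain = paste0("S", 1:10), chain = "B",
    start = seq(1, by = 60, length.out = 10),
    end = seq(60, by = 60, length.out = 10)))
  # barrel-1 residue x sushi-1 residue lands in that single cell
  one <- crosslink_set("FXIII-A", 600, "FXIII-B", 30)
  m1 <- domain_contact_matrix(one, list(`FXIII-A` = a_dom,
                                        `FXIII-B` = b_dom))
  expect_equal(sum(m1), 1L)
  expect_equal(m1["FXIII-A:beta-barrel-1", "FXIII-B:S1"], 1L)
  # empty input: all-zero matrix
  empty <- crosslink_set(character(0), integer(0), character(0), integer(0))
  expect_true(all(domain_contact_matrix(
    empty, list(`FXIII-A` = a_dom)) == 0))
  # 34 planted interface links sum to 34
  set.seed(11)
  n <- 34
  many <- crosslink_set(rep("FXIII-A", n), sample(1:731, n, replace = TRUE),
                        rep("FXIII-B", n), sample(1:600, n, replace = TRUE))
  m34 <- domain_contact_matrix(many, list(`FXIII-A` = a_dom,
                                          `FXIII-B` = b_dom))
  expect_equal(sum(m34), 34L)
})

test_that("export_restraints is deterministic and renders the DSS bounds", {
  xls <- crosslink_set("P", 10, "Q", 30)
  rs <- build_restraints(xls, list(P = "A", Q = "B"))
  f1 <- tempfile(); f2 <- tempfile()
  export_restraints(rs, f1, dialect = "haddock_tbl")
  txt <- readLines(f1)
  assigns <- grep("^assign", txt, value = TRUE)
  expect_length(assigns, 1L)
  expect_match(assigns, "3\\.0 0\\.0 21\\.0")
  expect_match(assigns, "segid A and resid 10")
  export_restraints(rs, f2, dialect = "haddock_tbl")
  expect_identical(readLines(f1), readLines(f2))
  expect_error(export_restraints(rs, tempfile(), dialect = "xplor"))

  # 64 synthetic restraints give 64 assign blocks
  m <- toy_model(2, 40, seed = 6)
  xls64 <- sample_crosslinks(m, n = 64, satisfied_fraction = 0.8, seed = 1)
  rs64 <- build_restraints(xls64, list(A = "A", B = "B"))
  f3 <- tempfile()
  export_restraints(rs64, f3, dialect = "haddock_tbl")
  expect_length(grep("^assign", readLines(f3)), 64L)
  # csv dialect round-trips through read.csv
  f4 <- tempfile(fileext = ".csv")
  export_restraints(rs64, f4, dialect = "csv")
  expect_equal(nrow(utils::read.csv(f4)), 64L)
})
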