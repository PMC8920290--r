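test_that("pixel coordinates are converted to microns at read time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,subject_id,x,y,CD3,CD8,FOXP3",
               "S1,P1,100,200,1,0,0",
               "S1,P1,50,75,0,1,0"), path)
  tab <- read_cell_table(path, coord_units = "pixels", mpp = 0.4977)
  expect_equal(tab$x, c(49.77, 24.885))
  expect_equal(tab$y, c(99.54, 37.3275))
  tab2 <- read_cell_table(path, coord_units = "microns")
  expect_equal(tab2$x, c(100, 50))
})

test_that("read errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,subject_id,x,CD3", "S1,P1,10,1"), path)
  expect_error(read_cell_table(path), "y")
  writeLines(c("sample_id,subject_id,x,y,CD3",
               "S1,P1,10,5,1", "S1,P1,abc,5,1"), path)
  expect_error(read_cell_table(path), "row 2")
  writeLines(c("sample_id,subject_id,x,y,CD3", "S1,P1,10,5,2"), path)
  expect_error(read_cell_table(path), "0/1")
})

test_that("write/read round trip preserves cells, flags and coordinates", {
  set.seed(31)
  xy <- runif_points(40)
  tab <- make_cells(xy, rbinom(40, 1, 0.3), compartment = "tumor")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cell_table(tab, path)
  back <- read_cell_table(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$x, tab$x, tolerance = 1e-6)
  expect_equal(back$y, tab$y, tolerance = 1e-6)
  expect_identical(back$CD3, tab$CD3)
  expect_identical(back$compartment, tab$compartment)
})

test_that("conflicting CD8+FOXP3+ phenotypes demote to CD3+ only", {
  df <- data.frame(sample_id = "S1", subject_id = "P1",
                   x = c(1, 2, 3), y = c(1, 2, 3),
                   CD3 = c(1L, 1L, 0L), CD8 = c(1L, 1L, 0L),
                   FOXP3 = c(1L, 0L, 1L))
  tab <- cell_table(df)
  res <- resolve_conflicting_phenotypes(tab)
  expect_equal(res$conflict_count, 1)
  expect_equal(res$table$CD3, c(1L, 1L, 0L))
  expect_equal(res$table$CD8, c(0L, 1L, 0L))
  expect_equal(res$table$FOXP3, c(0L, 0L, 1L))
  # location retained
  expect_equal(res$table$x, tab$x)
  # idempotent
  res2 <- resolve_conflicting_phenotypes(res$table)
  expect_equal(res2$conflict_count, 0)
  expect_identical(as.data.frame(res2$table), as.data.frame(res$table))
})

test_that("conflict count tallies every rewritten cell", {
  set.seed(5)
  df <- data.frame(sample_id = "S1", subject_id = "P1",
                   x = 1:10, y = 1:10,
                   CD3 = rep(1L, 10), CD8 = c(rep(1L, 3), rep(0L, 7)),
                   FOXP3 = c(rep(1L, 3), rep(0L, 7)))
  res <- resolve_conflicting_phenotypes(cell_table(df))
  expect_equal(res$conflict_count, 3)
})

test_that("compartment filtering keeps counts and signals empty samples", {
  xy <- runif_points(150)
  tab <- make_cells(xy, rbinom(150, 1, 0.2),
                    compartment = rep(c("tumor", "stroma"), c(100, 50)))
  expect_equal(nrow(filter_compartment(tab, "tumor")), 100)
  expect_equal(nrow(filter_compartment(tab, "stroma")), 50)
  expect_identical(filter_compartment(tab, "all"), tab)
  allstroma <- make_cells(runif_points(10), rep(0, 10), compartment = "stroma")
  expect_equal(nrow(filter_compartment(allstroma, "tumor")), 0)
  # without a compartment column only "all" is legal
  nocomp <- make_cells(runif_points(10), rep(0, 10))
  expect_error(filter_compartment(nocomp, "tumor"), "compartment")
})

test_that("phenotypes are strict marker conjunctions", {
  df <- data.frame(sample_id = "S1", subject_id = "P1",
                   x = 1:4, y = 1:4,
                   CD3 = c(1L, 0L, 1L, 0L), CD8 = c(1L, 1L, 0L, 0L))
  tab <- cell_table(df)
  expect_equal(nrow(phenotype_positive_cells(tab, "CD3")), 2)
  # CD8 without CD3 is not a cytotoxic T cell
  expect_equal(nrow(phenotype_positive_cells(tab, c("CD3", "CD8"))), 1)
  expect_error(phenotype_positive_cells(tab, character(0)), "at least one")
  expect_error(phenotype_positive_cells(tab, "PD1"), "unknown marker")
})

test_that("marker subsets are nested: |CD3| >= |CD3+CD8| on random tables", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    df <- data.frame(sample_id = "S", subject_id = "P",
                     x = runif(n), y = runif(n),
                     CD3 = rbinom(n, 1, 0.5), CD8 = rbinom(n, 1, 0.5))
    tab <- cell_table(df)
    expect_gte(nrow(phenotype_positive_cells(tab, "CD3")),
               nrow(phenotype_positive_cells(tab, c("CD3", "CD8"))))
  }
})

test_that("clinical table validation enforces the schema", {
  ok <- data.frame(subject_id = c("P1", "P2"), time_months = c(12, 30),
                   event = c(1, 0), age_dx = c(55, 61),
                   stage = c("III", "I"))
  cl <- clinical_table(ok)
  expect_s3_class(cl$stage, "factor")
  expect_equal(levels(cl$stage), c("I", "II", "III", "IV"))
  bad <- ok; bad$time_months[1] <- -2
  expect_error(clinical_table(bad), "time_months")
  bad <- ok; bad$subject_id <- c("P1", "P1")
  expect_error(clinical_table(bad), "duplicated")
  bad <- ok; bad$stage <- c("IIB", "I")
  expect_error(clinical_table(bad), "stage")
})
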