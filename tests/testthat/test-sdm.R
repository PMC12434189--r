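test_that("ESRI ASCII grid round-trips values, nodata and georeference", {
  v <- matrix(runif(12), 3, 4)
  v[2, 3] <- NA
  r <- toy_raster(v, xll = 104, yll = 24, cellsize = 0.5)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, f)
  back <- read_ascii_grid(f)
  expect_equal(back$values, v, tolerance = 1e-10)
  expect_equal(c(back$xll, back$yll, back$cellsize), c(104, 24, 0.5))
})

test_that("occurrence thinning enforces the distance floor and maximizes retention", {
  close_pair <- data.frame(record_id = c("a", "b"),
                           latitude = c(25, 25.004), longitude = c(105, 105))  # ~0.45 km
  th <- thin_occurrences(close_pair, 1, seed = 1)
  expect_equal(nrow(th), 1)

  grid <- expand.grid(latitude = 25 + (0:3) * 0.02, longitude = 105 + (0:3) * 0.02)
  grid$record_id <- sprintf("g%02d", seq_len(nrow(grid)))  # ~2.2 km spacing
  th2 <- thin_occurrences(grid, 1, seed = 1)
  expect_equal(nrow(th2), nrow(grid))

  set.seed(71)
  clustered <- data.frame(
    record_id = sprintf("c%03d", 1:60),
    latitude = 25 + rep(runif(6, 0, 0.5), each = 10) + runif(60, 0, 0.005),
    longitude = 105 + rep(runif(6, 0, 0.5), each = 10) + runif(60, 0, 0.005))
  th3 <- thin_occurrences(clustered, 1, seed = 9)
  d <- geosphere::distm(as.matrix(th3[, c("longitude", "latitude")])) / 1000
  diag(d) <- Inf
  expect_true(all(d >= 1))                       # exhaustive pairwise audit
  expect_equal(attr(th3, "retained"), nrow(th3))

  # invariant to input record order under the same seed
  th4 <- thin_occurrences(clustered[sample(60), ], 1, seed = 9)
  expect_equal(sort(th4$record_id), sort(th3$record_id))

  expect_warning(empty <- thin_occurrences(clustered[0, ], 1, seed = 1), "empty")
  expect_equal(nrow(empty), 0)
  expect_error(thin_occurrences(clustered, 0, seed = 1), class = "erodiv_precondition_error")
})

test_that("collinearity filter drops the right variables, audited exhaustively", {
  cm <- function(m, labels) {
    dimnames(m) <- list(labels, labels)
    m
  }
  two <- cm(matrix(c(1, 0.95, 0.95, 1), 2), c("v1", "v2"))
  expect_equal(length(collinearity_filter(two, 0.8)), 1)
  expect_equal(collinearity_filter(diag(4) |> cm(paste0("v", 1:4)), 0.8), paste0("v", 1:4))
  asym <- two; asym[1, 2] <- 0.5
  expect_error(collinearity_filter(asym, 0.8), class = "erodiv_schema_error")

  # planted redundant triplet among 6 variables
  labels <- paste0("bio", 1:6)
  m <- diag(6)
  m[1, 2] <- m[2, 1] <- 0.95
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.92
  m[4, 5] <- m[5, 4] <- 0.3
  m <- cm(m, labels)
  kept <- collinearity_filter(m, 0.8)
  # audit: no violating pair among kept
  sub <- abs(m[kept, kept]); diag(sub) <- 0
  expect_true(all(sub <= 0.8))
  # audit: kept set is maximal among all subsets without a violating pair
  all_ok_sizes <- vapply(seq_len(2^6) - 1, function(mask) {
    sel <- labels[bitwAnd(mask, 2^(0:5)) > 0]
    if (length(sel) < 2) return(length(sel))
    s <- abs(m[sel, sel]); diag(s) <- 0
    if (all(s <= 0.8)) length(sel) else 0L
  }, numeric(1))
  expect_equal(length(kept), max(all_ok_sizes))
})

test_that("binarize/categorize: boundary conventions and mutual consistency", {
  v <- matrix(c(0.3892, 0.3893, 0.0, 0.5, 0.7, 0.75, NA, 1.0, 0.4999), 3, 3)
  r <- toy_raster(v)
  b <- binarize_suitability(r, 0.3893)
  expect_equal(b$values[1, 1], 0)   # just below MTSS
  expect_equal(b$values[2, 1], 1)   # exactly MTSS is suitable
  expect_true(is.na(b$values[1, 3]))
  ct <- categorize_suitability(r, 0.3893)
  lg <- attr(ct, "legend")
  expect_equal(unname(lg[as.character(ct$values[1, 2])]), "moderate")  # 0.5 boundary
  expect_equal(unname(lg[as.character(ct$values[3, 2])]), "high")      # 0.75
  expect_equal(unname(lg[as.character(ct$values[3, 1])]), "unsuitable")
  expect_equal(unname(lg[as.character(ct$values[2, 3])]), "high")      # 1.0 included
  expect_equal(unname(lg[as.character(ct$values[3, 3])]), "low")       # 0.4999
  # category != unsuitable <=> binary suitable
  expect_identical(ct$values > 0, b$values == 1)
  expect_error(categorize_suitability(r, 0.6), class = "erodiv_domain_error")

  allna <- toy_raster(matrix(NA_real_, 2, 2))
  expect_true(all(is.na(binarize_suitability(allna, 0.3893)$values)))
})

test_that("change maps follow the truth table and partition the cells", {
  cur <- toy_raster(matrix(c(1, 1, 0, 0, NA, 1), 2, 3))
  fut <- toy_raster(matrix(c(1, 0, 1, 0, 1, NA), 2, 3))
  cm <- change_map(cur, fut)
  lg <- attr(cm, "legend")
  expect_equal(unname(lg[as.character(cm$values[1, 1])]), "stable")
  expect_equal(unname(lg[as.character(cm$values[2, 1])]), "contraction")
  expect_equal(unname(lg[as.character(cm$values[1, 2])]), "expansion")
  expect_equal(unname(lg[as.character(cm$values[2, 2])]), "absent")
  expect_true(is.na(cm$values[1, 3]) && is.na(cm$values[2, 3]))

  shifted <- toy_raster(fut$values, xll = 1)
  expect_error(change_map(cur, shifted), class = "erodiv_georeference_error")

  # identical maps: no contraction, no expansion
  cm0 <- change_map(cur, cur)
  a0 <- area_summary(cm0, 1)
  expect_equal(a0$cells[a0$category %in% c("contraction", "expansion")], c(0, 0))

  # random pair: categories partition the non-nodata cells (cellwise recount)
  set.seed(72)
  for (rep in 1:10) {
    c1 <- toy_raster(matrix(sample(c(0, 1, NA), 30, TRUE, prob = c(.4, .4, .2)), 5, 6))
    c2 <- toy_raster(matrix(sample(c(0, 1, NA), 30, TRUE, prob = c(.4, .4, .2)), 5, 6))
    cmr <- change_map(c1, c2)
    a <- area_summary(cmr, 1)
    expect_equal(sum(a$cells), sum(!is.na(cmr$values)))
    expect_equal(sum(!is.na(cmr$values)),
                 sum(!is.na(c1$values) & !is.na(c2$values)))
    oracle <- sum(!is.na(c1$values) & !is.na(c2$values) & c1$values == 1 & c2$values == 0)
    expect_equal(a$cells[a$category == "contraction"], oracle)
  }
})

test_that("area accounting in thousands of km^2, with per-row latitude weights", {
  v <- matrix(0, 2, 10)
  v[1, 1:10] <- 1   # 10 contraction cells after change vs all-zero future
  cur <- toy_raster(v)
  fut <- toy_raster(matrix(0, 2, 10))
  a <- area_summary(change_map(cur, fut), 1)
  expect_equal(a$area_1e3_km2[a$category == "contraction"], 0.01)
  expect_equal(a$area_1e3_km2[a$category == "expansion"], 0)
  # per-row vector equals the row-wise sum oracle
  aw <- area_summary(change_map(cur, fut), c(2, 0.5))
  expect_equal(aw$area_1e3_km2[aw$category == "contraction"], 10 * 2 / 1000)
  expect_equal(aw$area_1e3_km2[aw$category == "absent"], 10 * 0.5 / 1000)
  expect_error(area_summary(change_map(cur, fut), c(1, 1, 1)), class = "erodiv_domain_error")
})

test_that("locality survival uses the containing cell and flags coverage gaps", {
  v <- matrix(c(1, 0, NA, 1), 2, 2)  # row 1 = top
  fut <- toy_raster(v, xll = 0, yll = 0, cellsize = 1)
  loc <- data.frame(sample_id = c("a", "b", "c", "d"),
                    locality_code = c("TL", "BL", "TR", "BR"),
                    latitude = c(1.5, 0.5, 1.5, 0.5),
                    longitude = c(0.5, 0.5, 1.5, 1.5))
  expect_warning(sv <- locality_survival(fut, loc), "nodata")
  got <- setNames(sv$survived, sv$locality)
  expect_true(got[["TL"]])    # value 1
  expect_false(got[["BL"]])   # value 0
  expect_false(got[["TR"]])   # nodata -> lost
  expect_true(got[["BR"]])    # value 1

  out <- data.frame(sample_id = "x", locality_code = "OUT",
                    latitude = 5, longitude = 5)
  err <- tryCatch(locality_survival(fut, out), error = identity)
  expect_s3_class(err, "erodiv_locality_coverage_error")
  expect_match(conditionMessage(err), "OUT")
})
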