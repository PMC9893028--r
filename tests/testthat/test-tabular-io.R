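test_that("phenology reader converts calendar dates to day-of-year", {
  f <- write_lines_csv(c("species_id,site_id,event,year,date",
                         "sp1,Beijing,LCD,1990,1990-10-12",
                         "sp2,Beijing,FLD,1992,75"))
  df <- read_phenology(f)
  expect_equal(df$doy[df$species_id == "sp1"], 285)  # 1990 is not a leap year
  expect_equal(df$doy[df$species_id == "sp2"], 75)
  # leap year: Feb 29 is DOY 60
  f2 <- write_lines_csv(c("species_id,site_id,event,year,date",
                          "sp1,a,LCD,2000,2000-02-29"))
  expect_equal(read_phenology(f2)$doy, 60)
})

test_that("phenology reader handles empty tables and rejects bad input", {
  f <- write_lines_csv("species_id,site_id,event,year,date")
  expect_equal(nrow(read_phenology(f)), 0)
  dup <- write_lines_csv(c("species_id,site_id,event,year,date",
                           "sp1,Beijing,LCD,1990,1990-10-12",
                           "sp1,Beijing,LCD,1990,1990-10-13"))
  expect_error(read_phenology(dup), "duplicate")
  bad <- write_lines_csv(c("species_id,site_id,event,year,date",
                           "sp1,Beijing,LCD,1990,not-a-date"))
  expect_error(read_phenology(bad), "line")
  badev <- write_lines_csv(c("species_id,site_id,event,year,date",
                             "sp1,Beijing,BUD,1990,100"))
  expect_error(read_phenology(badev), "FLD or LCD")
})

test_that("climate reader validates physics and keyed retrieval", {
  hdr <- "site_id,date,tmax,tmin,pre,ins,win"
  rows <- sprintf("s1,%s,10,2,1,10,2",
                  seq(as.Date("1990-01-01"), as.Date("1990-12-31"), "day"))
  cl <- read_climate(write_lines_csv(c(hdr, rows)))
  expect_equal(nrow(cl), 365)
  # interleaved sites both retrievable
  two <- read_climate(write_lines_csv(c(hdr,
    "a,1990-01-01,5,1,0,8,1", "b,1990-01-01,7,2,0,9,1",
    "a,1990-01-02,5,1,0,8,1", "b,1990-01-02,7,2,0,9,1")))
  expect_equal(sum(two$site_id == "a"), 2)
  expect_equal(sum(two$site_id == "b"), 2)
  expect_error(read_climate(write_lines_csv(c(hdr, "s1,1990-01-01,10,2,-1,10,2"))),
               "negative pre")
  expect_error(read_climate(write_lines_csv(c(hdr, "s1,1990-01-01,2,10,1,10,2"))),
               "tmin > tmax")
  expect_warning(read_climate(write_lines_csv(c(hdr,
    "s1,1990-01-01,10,2,1,10,2", "s1,1990-01-03,10,2,1,10,2"))),
    "missing day")
})

test_that("occurrence reader enforces the temperature ordering", {
  hdr <- "species_id,lon,lat,mat,tmax_warm,tmin_cold,map,srad"
  ok <- read_occurrences(write_lines_csv(c(hdr, "sp1,110,34,10,25,-5,500,4000")))
  expect_equal(nrow(ok), 1)
  expect_error(read_occurrences(write_lines_csv(c(hdr,
    "sp1,110,34,10,5,-5,500,4000"))), "tmin_cold")
  expect_error(read_occurrences(write_lines_csv(c(hdr,
    "sp1,110,34,10,25,-5,-1,4000"))), "negative map")
})

test_that("tree reader validates labels and branch lengths", {
  f <- write_lines_csv("((A:1,B:1):1,C:2);")
  tr <- read_tree(f)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(sum(tr$edge.length), 5)
  expect_error(read_tree(write_lines_csv("((A:1,A:1):1,C:2);")), "duplicate")
  expect_error(read_tree(write_lines_csv("(A,B);")), "branch length")
})

test_that("write/read round trips preserve values and distances", {
  set.seed(4)
  df <- data.frame(id = letters[1:5], x = rnorm(5), p = runif(5) * 1e-7)
  f <- tempfile(fileext = ".csv")
  write_result_table(df, f)
  back <- read_result_table(f)
  expect_equal(back$x, df$x, tolerance = 1e-12)
  expect_equal(back$p, df$p, tolerance = 1e-12)

  tr <- gen_yule_tree(12, 1, seed = 8)
  fn <- tempfile(fileext = ".nwk")
  write_tree(tr, fn)
  tr2 <- read_tree(fn)
  D1 <- patristic_distances(tr)
  D2 <- patristic_distances(tr2)[rownames(D1), colnames(D1)]
  expect_equal(D1, D2, tolerance = 1e-10)
})
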