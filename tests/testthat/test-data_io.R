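specs18 <- default_character_specs()

write_obs_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("strain_id,individual_id,character_id,side,value", lines),
             path)
  path
}

test_that("observation CSVs are read, validated and round-tripped", {
  path <- write_obs_csv(c("X,X-1,02,none,4", "X,X-2,02,none,5",
                          "Y,Y-1,02,none,4"))
  tab <- read_observations(path, specs18)
  expect_s3_class(tab, "obs_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "strains"), c("X", "Y"))
  expect_equal(tab$value, c(4L, 5L, 4L))

  # empty value field becomes a missing observation
  path2 <- write_obs_csv(c("X,X-1,02,none,4", "X,X-2,02,none,"))
  tab2 <- read_observations(path2, specs18)
  expect_identical(tab2$missing, c(FALSE, TRUE))
  expect_true(is.na(tab2$value[2]))

  # write -> read is the identity
  out <- withr::local_tempfile(fileext = ".csv")
  write_observations(tab2, out)
  again <- read_observations(out, specs18)
  expect_identical(as.data.frame(again), as.data.frame(tab2))
})

test_that("laterality and character ids are validated on ingest", {
  # character 12 is bilateral: a side is accepted
  ok <- write_obs_csv("X,X-1,12,left,30")
  expect_silent(tab <- read_observations(ok, specs18))
  expect_equal(tab$side, "left")
  # character 01 is not: a side is a validation error
  bad <- write_obs_csv("X,X-1,01,left,1")
  expect_error(read_observations(bad, specs18), "non-bilateral")
  # unknown character ids are rejected
  unk <- write_obs_csv("X,X-1,99,none,1")
  expect_error(read_observations(unk, specs18), "unknown character")
  # value XOR missing flag
  expect_error(observation_table(
    data.frame(strain_id = "X", individual_id = "X-1", character_id = "01",
               side = "none", value = 1L, missing = TRUE), specs18),
    "XOR")
})

test_that("observation counts per cell are conserved and reported", {
  path <- write_obs_csv(c("X,X-1,02,none,4", "X,X-2,02,none,",
                          "Y,Y-1,02,none,5", "Y,Y-1,03,none,20"))
  tab <- read_observations(path, specs18)
  s <- summarize_observations(tab)
  expect_equal(s$n_obs[s$strain_id == "X" & s$character_id == "02"], 1L)
  expect_equal(s$n_missing[s$strain_id == "X" & s$character_id == "02"], 1L)
  expect_equal(sum(s$n_obs) + sum(s$n_missing), nrow(tab))
})

test_that("trees round-trip through Newick with identical splits", {
  path <- withr::local_tempfile(fileext = ".nwk")
  two <- ape::read.tree(text = "(A,B);")
  write_tree(two, path)
  expect_equal(sort(read_tree(path)$tip.label), c("A", "B"))

  rooted <- ape::read.tree(text = "((A,B),(C,D));")
  write_tree(rooted, path)
  expect_setequal(tree_clades(read_tree(path)), tree_clades(rooted))

  # dendrogram heights survive as branch lengths: merges at heights 1 and 2
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma(d)
  write_tree(dend, path)
  back <- read_tree(path)
  depths <- ape::node.depth.edgelength(back)
  tip_depth <- max(depths[seq_len(3)])
  # root-to-node depths recover the merge heights 1 and 2
  node_heights <- sort(tip_depth - depths[4:5])
  expect_equal(node_heights, c(1, 2), tolerance = 1e-12)
})

test_that("NEXUS export writes a standard-format 0/1 matrix", {
  m <- matrix(c(0L, 1L, 1L, 0L, 1L, 1L), 3, 2,
              dimnames = list(c("X", "Y", "Z"), c("01", "02")))
  bm <- list(taxa = rownames(m), characters = colnames(m), states = m,
             uninformative = character(0))
  class(bm) <- "binary_taxon_matrix"
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus_matrix(bm, path)
  txt <- readLines(path)
  expect_true(any(grepl("DATATYPE=STANDARD", txt)))
  expect_true(any(grepl("NTAX=3 NCHAR=2", txt)))
  expect_true(any(grepl("^    X +00", txt)))
})
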