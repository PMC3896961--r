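test_that("cleaning normalises case, whitespace, digits and U/T", {
  expect_identical(unname(clean_sequence("atg gug\ncac")), "ATGGTGCAC")
  expect_identical(unname(clean_sequence("1 atg\n2 uaa")), "ATGTAA")
  expect_identical(unname(clean_sequence("")), "")
})

test_that("strict cleaning reports the first bad character and position", {
  err <- expect_error(clean_sequence("ATGNAA"), "'N'")
  expect_match(conditionMessage(err), "position 4")
  expect_warning(out <- clean_sequence("ATGNAA", strict = FALSE), "'N'")
  expect_identical(unname(out), "ATGNAA")
})

test_that("cleaning is idempotent on arbitrary messy input", {
  set.seed(11)
  for (i in 1:50) {
    raw <- random_messy(sample(0:120, 1))
    once <- clean_sequence(raw, strict = FALSE)
    expect_identical(suppressWarnings(clean_sequence(once, strict = FALSE)),
                     once, label = paste("idempotence on", encodeString(raw)))
  }
})

test_that("frame-0 triplet split drops the trailing partial codon", {
  expect_identical(to_triplets("ATGGTGCAC"), c("ATG", "GTG", "CAC"))
  expect_message(tr <- to_triplets("ATGGTGCACC"), "1 trailing")
  expect_identical(tr, c("ATG", "GTG", "CAC"))
  expect_identical(to_triplets("AT"), character(0))
  expect_identical(to_triplets(""), character(0))
})

test_that("triplet count and concatenation invariants hold at random lengths", {
  set.seed(12)
  for (i in 1:40) {
    n <- sample(0:300, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    trips <- suppressMessages(to_triplets(seq))
    expect_length(trips, n %/% 3)
    expect_identical(paste(trips, collapse = ""),
                     substr(seq, 1, 3 * (n %/% 3)))
  }
})

test_that("plot set maps triplet i to (i, weight)", {
  ps <- to_plot_set("GCTGCC", TBL)
  expect_equal(ps$index, 1:2)
  expect_equal(ps$weight, c(1.1, 1.2))

  human <- load_betaglobin()["Human"]
  ph <- to_plot_set(human, TBL)
  expect_identical(attr(ph, "id"), "Human")
  expect_equal(nrow(ph), 148)
  expect_equal(ph$weight[1:3], c(20.1, 19.4, 9.2))

  empty <- to_plot_set("", TBL)
  expect_equal(nrow(empty), 0)
})

test_that("permuting a sequence's triplets permutes the plot-set weights", {
  set.seed(13)
  trips <- suppressMessages(to_triplets(unname(random_cds(30, seed = 5))))
  perm <- sample(length(trips))
  w1 <- to_plot_set(paste(trips, collapse = ""), TBL)$weight
  w2 <- to_plot_set(paste(trips[perm], collapse = ""), TBL)$weight
  expect_equal(w2, w1[perm])
})

test_that("plot-set TSV round-trips exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  ps <- to_plot_set("GCTGCCTAA", TBL)
  write_plot_set(ps, f)
  lines <- readLines(f)
  expect_identical(lines[1], "index\tweight")
  expect_identical(lines[2], "1\t1.1")
  back <- read_plot_set(f)
  expect_equal(back$index, ps$index)
  expect_equal(back$weight, ps$weight)

  write_plot_set(to_plot_set("", TBL), f)
  expect_identical(readLines(f), "index\tweight")
})

test_that("figures are rendered for full and empty plot sets", {
  f <- withr::local_tempfile(fileext = ".png")
  render_plot(to_plot_set(load_betaglobin()["Human"], TBL), f)
  expect_gt(file.size(f), 0)
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_plot(to_plot_set("", TBL), f2, title = "empty")
  expect_gt(file.size(f2), 0)
  expect_error(render_plot(to_plot_set("", TBL), "x.pdf"), "pdf")
})

test_that("FASTA write/read round-trips the benchmark records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- load_betaglobin()
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_identical(back, seqs)
})

test_that("FASTA ids stop at the first whitespace", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1 homo sapiens beta globin", "ATGGTG", "CAC", "",
               ">seq2", "gcugcc"), f)
  seqs <- read_fasta(f)
  expect_identical(names(seqs), c("seq1", "seq2"))
  expect_identical(unname(seqs), c("ATGGTGCAC", "GCTGCC"))
})
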