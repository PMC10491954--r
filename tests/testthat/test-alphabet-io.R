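test_that("alphabets put the gap last and encode/decode are inverse", {
  for (kind in c("protein", "rna")) {
    ab <- make_alphabet(kind)
    expect_equal(ab$q, if (kind == "protein") 21L else 5L)
    expect_identical(ab$symbols[ab$q], "-")
    s <- paste(ab$symbols, collapse = "")
    expect_identical(decode_seq(encode_seq(s, ab), ab), s)
  }
  ab <- toy_alphabet(4)
  expect_identical(ab$symbols, c("A", "C", "D", "-"))
})

test_that("RNA queries reject T unless T->U normalization is on", {
  ab <- make_alphabet("rna")
  expect_error(encode_seq("ACGT", ab), "symbol error")
  abu <- make_alphabet("rna", t_to_u = TRUE)
  expect_identical(encode_seq("ACGT", abu), c(1L, 2L, 3L, 4L))
  expect_identical(encode_seq("ACGU", ab), c(1L, 2L, 3L, 4L))
})

test_that("A2M parsing assigns inserts to the right boundary", {
  msa <- msa_from_a2m(c("AC-a", "ACGa"))
  ab <- msa$alphabet
  expect_equal(msa$L, 3L)
  r1 <- msa$rows[[1]]
  expect_identical(r1$match_symbols,
                   encode_seq(c("A", "C", "-"), ab))
  expect_identical(r1$insert_runs[[4]], encode_seq("A", ab))
  expect_identical(lengths(r1$insert_runs), c(0L, 0L, 0L, 1L))
  expect_equal(sum(msa$weights > 0), 2L)
})

test_that("A2M '.' padding is dropped and case determines state", {
  msa <- msa_from_a2m(c("A.d.C", "AwyC"))
  expect_equal(msa$L, 2L)
  expect_identical(lengths(msa$rows[[1]]$insert_runs), c(0L, 1L, 0L))
  expect_identical(lengths(msa$rows[[2]]$insert_runs), c(0L, 2L, 0L))
})

test_that("Stockholm RF masks match columns; inserts land between them", {
  path <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0",
               "seq1   AC.G",
               "seq2   A-gG",
               "#=GC RF xx.x",
               "//"), path)
  msa <- read_seed(path, "stockholm")
  expect_equal(msa$L, 3L)
  expect_identical(lengths(msa$rows[[1]]$insert_runs), c(0L, 0L, 0L, 0L))
  expect_identical(msa$rows[[2]]$insert_runs[[3]],
                   encode_seq("G", msa$alphabet))
  expect_identical(msa$rows[[2]]$match_symbols[2], msa$alphabet$gap)
})

test_that("an all-gap row is accepted with a warning and reconstructs empty", {
  expect_message(msa <- msa_from_a2m(c("AC-", "---")), "empty unaligned")
  expect_identical(reconstruct_row(msa$rows[[2]], msa), integer(0))
})

test_that("format errors are loud: ragged rows, bad symbols, empty seeds", {
  expect_error(msa_from_a2m(c("AC", "ACG")), "ragged")
  expect_error(msa_from_a2m(c("AC1", "ACG")), "symbol error.*column 3")
  path <- withr::local_tempfile(fileext = ".a2m")
  writeLines(character(0), path)
  expect_error(read_seed(path, "a2m"), "empty-seed")
  path2 <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("seq1 AC", "//"), path2)
  expect_error(read_seed(path2, "stockholm"), "RF")
})

test_that("query reading encodes, records N, and rejects gaps", {
  ab <- make_alphabet("rna")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1", "ACGU"), path)
  qs <- read_queries(path, ab)
  expect_identical(qs[[1]]$seq, c(1L, 2L, 3L, 4L))
  expect_equal(qs[[1]]$N, 4L)

  writeLines(c(">q1", "AC-GU"), path)
  expect_error(read_queries(path, ab), "input error.*gap")

  writeLines(character(0), path)
  expect_identical(read_queries(path, ab), list())
})

test_that("duplicate FASTA ids get occurrence suffixes", {
  ab <- make_alphabet("rna")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q", "ACGU", ">q", "GGGG"), path)
  expect_message(qs <- read_queries(path, ab), "duplicate")
  expect_identical(vapply(qs, `[[`, "", "id"), c("q", "q_2"))
})

test_that("write_alignment renders matches, gaps and insertions", {
  ab <- make_alphabet("protein")
  mk <- function(x, n, chars) list(id = "r", x = x, n = n,
                                   query = encode_seq(chars, ab))
  path <- withr::local_tempfile(fileext = ".a2m")

  write_alignment(list(mk(c(1, 1, 1), c(1, 2, 3), "ACD")), path, "a2m", ab)
  expect_identical(readLines(path)[2], "ACD")

  write_alignment(list(mk(c(1, 0, 1), c(1, 1, 2), "AC")), path, "a2m", ab)
  expect_identical(readLines(path)[2], "A-C")

  write_alignment(list(mk(c(1, 1), c(1, 3), "ACD")), path, "a2m", ab)
  expect_identical(readLines(path)[2], "AcD")
  write_alignment(list(mk(c(1, 1), c(1, 3), "ACD")), path, "fasta", ab)
  expect_identical(readLines(path)[2], "AD")

  expect_error(write_alignment(list(mk(c(1, 1), c(1, 2), "AC"),
                                    mk(c(1, 1, 1), c(1, 2, 3), "ACD")),
                               path, "a2m", ab),
               "internal error")
})

test_that("A2M write -> read round trip recovers (x, n) exactly", {
  ab <- make_alphabet("protein")
  set.seed(41)
  for (rep in 1:25) {
    L <- sample(2:6, 1); N <- L + sample(0:4, 1)
    st <- random_feasible_state(L, N)
    query <- sample.int(ab$q - 1L, N, replace = TRUE)
    res <- list(id = "r", x = st$x, n = st$n, query = query)
    path <- withr::local_tempfile(fileext = ".a2m")
    write_alignment(list(res), path, "a2m", ab)
    msa <- read_seed(path, "a2m", ab)
    expect_equal(msa$L, L)
    row <- msa$rows[[1]]
    # reconstructed unaligned sequence must be the query
    expect_identical(reconstruct_row(row, msa), query)
    # and the pointer walk must reproduce the full pointer vector
    expect_identical(pointer_trajectory(row, msa), as.integer(st$n))
    expect_identical(row$match_symbols,
                     as.integer(ifelse(st$x == 1L, query[pmax(st$n[2:(L + 1L)], 1L)], ab$q)))
  }
})

test_that("reconstruction length = non-gap matches + total insert length", {
  msa <- msa_from_a2m(c("aAC-Gg", "A-GwyC"))
  for (r in msa$rows) {
    expect_length(reconstruct_row(r, msa),
                  sum(r$match_symbols != msa$alphabet$gap) + sum(lengths(r$insert_runs)))
  }
})
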