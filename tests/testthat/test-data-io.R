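A <- pb_alphabet()

test_that("a minimal hand-written PDB yields one chain and one window", {
  path <- system.file("extdata", "synthetic_penta.pdb", package = "pbcoords")
  chains <- read_backbone(path)
  expect_length(chains, 1)
  ch <- chains[[1]]
  expect_equal(ch$length, 5)
  expect_equal(nchar(ch$sequence), 5)
  wins <- iter_fragments(ch)
  expect_length(wins, 1)
  expect_equal(wins[[1]]$start, 0L)
  expect_identical(assign_pb(wins[[1]]$fragment, A), "M")
})

test_that("backbone write/read round-trips coordinates to format precision", {
  corpus <- generate_corpus(synthetic_corpus_config(n_chains = 2,
                                                    length_range = c(12, 15)),
                            seed = 401, A)
  tmp <- tempfile(fileext = ".pdb")
  write_backbone(corpus, tmp)
  back <- read_backbone(tmp)
  expect_length(back, 2)
  for (k in 1:2) {   # chain ids are remapped to single PDB characters
    expect_equal(back[[k]]$coords, corpus[[k]]$coords, tolerance = 2e-3,
                 ignore_attr = TRUE)
    expect_identical(back[[k]]$sequence, corpus[[k]]$sequence)
  }
  unlink(tmp)
})

test_that("a CA-CA gap breaks the chain and suppresses spanning windows", {
  ch <- generate_corpus(synthetic_corpus_config(n_chains = 1,
                                                length_range = c(10, 10)),
                        seed = 402, A)[[1]]
  # translate residues 4..10 far away: 10 A gap between residues 3 and 4
  ch$coords[10:30, 1] <- ch$coords[10:30, 1] + 50
  wins <- iter_fragments(ch)
  starts <- vapply(wins, `[[`, integer(1), "start")
  expect_true(all(starts %in% c(0:5)))
  # runs are 1..3 and 4..10: only the 7-residue tail yields windows
  expect_equal(length(wins), 3)
  expect_equal(starts, 3:5)
})

test_that("window counts equal brute-force enumeration on broken chains", {
  set.seed(403)
  for (k in 1:50) {
    L <- sample(5:40, 1)
    ok <- runif(L) > 0.15
    ch <- list(id = "x", length = L,
               sequence = paste(rep("A", L), collapse = ""),
               coords = matrix(rnorm(9 * L, sd = 0.1), 3 * L, 3) +
                 matrix(rep(seq_len(L) * 2, each = 9), 3 * L, 3)[, 1] * 0,
               atom_ok = ok)
    # keep consecutive CA atoms close so only atom_ok drives the runs
    ch$coords <- matrix(0, 3 * L, 3)
    ch$coords[, 1] <- rep(seq_len(L), each = 3) + rep(c(0, 0.3, 0.6), L)
    wins <- iter_fragments(ch)
    # oracle: enumerate starts where 5 consecutive residues are all intact
    brute <- sum(vapply(seq_len(max(L - 4, 0)), function(s)
      all(ok[s:(s + 4)]), logical(1)))
    expect_equal(length(wins), brute)
  }
})

test_that("missing backbone atoms flag the residue and suppress windows", {
  ch <- generate_corpus(synthetic_corpus_config(n_chains = 1,
                                                length_range = c(9, 9)),
                        seed = 404, A)[[1]]
  tmp <- tempfile(fileext = ".pdb")
  write_backbone(ch, tmp)
  txt <- readLines(tmp)
  # drop residue 5's CA
  drop <- grep("^ATOM", txt)[13 + 1]  # atom 14 = CA of residue 5
  writeLines(txt[-drop], tmp)
  back <- read_backbone(tmp)[[1]]
  expect_false(back$atom_ok[5])
  starts <- vapply(iter_fragments(back), `[[`, integer(1), "start")
  expect_false(any(starts <= 4 & starts + 4 >= 4))
  unlink(tmp)
})

test_that("fragment tables carry coherent labels and distances", {
  corpus <- generate_corpus(synthetic_corpus_config(n_chains = 3),
                            seed = 405, A)
  fr <- corpus_fragments(corpus, A, flank = 2)
  expect_equal(length(fr$seq), sum(vapply(corpus, function(ch)
    ch$length - 4L, integer(1))))
  expect_equal(ncol(fr$D), 16)
  expect_true(all(nchar(fr$context) == 9))
  # label matches the distance argmin
  expect_identical(fr$label_rmsd,
                   toupper(letters[1:16][apply(fr$D, 1, which.min)]))
  tmp <- tempfile(fileext = ".tsv")
  write_assignments(fr, tmp)
  tab <- utils::read.delim(tmp)
  expect_equal(nrow(tab), length(fr$seq))
  expect_identical(tab$label_rmsd, fr$label_rmsd)
  unlink(tmp)
})
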