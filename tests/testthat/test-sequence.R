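test_that("variant strings parse into ordered substitution tables", {
  subs <- parse_variant_spec("E114Q+E123Q+E126Q+E137Q+E139Q")
  expect_equal(nrow(subs), 5L)
  expect_equal(subs$position, c(114L, 123L, 126L, 137L, 139L))
  expect_true(all(subs$wt == "E") && all(subs$new == "Q"))
  expect_equal(nrow(parse_variant_spec("")), 0L)
  expect_equal(nrow(parse_variant_spec(NULL)), 0L)
  # unsorted input comes back position-sorted
  expect_equal(parse_variant_spec("E123Q+E114Q")$position, c(114L, 123L))
  expect_error(parse_variant_spec("E114X"), "non-standard")
  expect_error(parse_variant_spec("114Q"), "malformed")
  expect_error(parse_variant_spec("E114Q+E114A"), "duplicate")
})

test_that("applying a variant changes exactly the listed positions", {
  wt <- asyn_sequence()
  expect_equal(nchar(wt), 140L)
  subs <- parse_variant_spec("E114Q+E123Q+E126Q+E137Q+E139Q")
  mut <- apply_variant(wt, subs)
  expect_equal(nchar(mut), 140L)
  diffs <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diffs, c(114L, 123L, 126L, 137L, 139L))
  expect_true(all(strsplit(mut, "")[[1]][diffs] == "Q"))
  expect_identical(apply_variant(wt, parse_variant_spec("")), wt)
  expect_error(apply_variant(wt, parse_variant_spec("D114Q")), "mismatch")
})

test_that("acidic site enumeration matches the sequence composition", {
  wt <- wt_spec(); q5 <- q5_spec()
  tail <- enumerate_acidic_sites(wt, "tail_only")
  expect_equal(nrow(tail), 15L)
  all25 <- enumerate_acidic_sites(wt, "all_acidic")
  expect_equal(nrow(all25), 25L)
  expect_equal(nrow(enumerate_acidic_sites(q5, "all_acidic")), 20L)
  expect_equal(nrow(enumerate_acidic_sites(wt, "all_acidic",
                                           include_cterm = FALSE)), 24L)
  # deterministic position ordering, C-terminus last
  expect_false(is.unsorted(all25$position))
  expect_equal(all25$kind[25], "Cterm")
  # subsets: tail within all; 5Q within wt
  key <- function(s) paste(s$position, s$kind)
  expect_true(all(key(tail) %in% key(all25)))
  expect_lt(nrow(tail), nrow(all25))
  expect_true(all(key(enumerate_acidic_sites(q5, "all_acidic")) %in%
                    key(all25)))
})

test_that("full titratable enumeration counts His/Lys/Tyr and termini", {
  sites <- enumerate_all_titratable(wt_spec())
  expect_equal(sum(sites$kind == "His"), 1L)
  expect_equal(sites$position[sites$kind == "His"], 50L)
  expect_equal(sum(sites$kind == "Lys"), 15L)
  expect_equal(sum(sites$kind == "Tyr"), 4L)
  expect_equal(sum(sites$kind %in% c("Nterm", "Cterm")), 2L)
  expect_equal(nrow(sites), 24L + 1L + 15L + 4L + 2L)
  # acid/base split follows the chemistry
  expect_setequal(unique(sites$kind[sites$acid]),
                  c("Asp", "Glu", "Tyr", "Cterm"))
  expect_setequal(unique(sites$kind[!sites$acid]),
                  c("His", "Lys", "Nterm"))
})

test_that("regional pKa assignment reproduces the NMR-derived scheme", {
  wt <- wt_spec()
  set <- assign_pkas(enumerate_acidic_sites(wt, "all_acidic"),
                     "croke_regional")
  s <- set$sites
  expect_equal(s$pKa_assigned[s$position == 126], 4.6)  # tail Glu
  expect_equal(s$pKa_assigned[s$position == 2], 3.6)    # N-terminal Asp
  expect_equal(s$pKa_assigned[s$position == 115], 4.2)  # tail Asp
  expect_equal(s$pKa_assigned[s$position == 35], 4.2)   # core Glu
  expect_equal(round(mean(s$pKa_assigned), 1), 4.3)
  q5set <- assign_pkas(enumerate_acidic_sites(q5_spec(), "all_acidic"),
                       "croke_regional")
  expect_equal(round(mean(q5set$sites$pKa_assigned), 1), 4.2)
  # other schemes
  intr <- assign_pkas(enumerate_all_titratable(wt), "intrinsic")
  expect_equal(intr$sites$pKa_assigned, intr$sites$pKa0)
  unif <- assign_pkas(enumerate_acidic_sites(wt), 4.5)
  expect_true(all(unif$sites$pKa_assigned == 4.5))
  expect_error(assign_pkas(enumerate_all_titratable(wt), "croke_regional"),
               "not covered")
  # C-terminal override is honored
  cset <- assign_pkas(enumerate_acidic_sites(wt), "croke_regional",
                      cterm_pka = 3.8)
  expect_equal(cset$sites$pKa_assigned[cset$sites$kind == "Cterm"], 3.8)
})

test_that("site counts survive a FASTA round trip", {
  skip_if_not_installed("Biostrings")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(asyn = asyn_sequence()), path)
  back <- read_fasta(path)
  expect_equal(unname(back[1]), asyn_sequence())
  spec2 <- protein_spec("rt", sequence = unname(back[1]))
  expect_equal(nrow(enumerate_acidic_sites(spec2, "all_acidic")), 25L)
  # the shipped fixture carries the same sequence
  pkg_fasta <- system.file("extdata", "asyn_wt.fasta", package = "pkashift")
  expect_equal(unname(read_fasta(pkg_fasta)[1]), asyn_sequence())
})
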