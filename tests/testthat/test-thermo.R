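test_that("stack lookup is a total, pure function over the 16 WC stacks", {
  p <- nn_params()
  dinucs <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                            paste0))
  vals <- vapply(dinucs, nn_stack_dG, numeric(1), params = p)
  expect_length(vals, 16L)
  expect_true(all(is.finite(vals) & vals < 0))
  # reverse-complement symmetry of the table
  rc <- vapply(dinucs, mirscan::rna_revcomp, character(1))
  expect_equal(unname(vals[rc]), unname(vals))
  expect_identical(nn_stack_dG("GC"), nn_stack_dG("GC"))
  expect_equal(nn_stack_dG("AA"), p$stack[["AA"]])
  expect_error(nn_stack_dG("AT"), "non-RNA")
  expect_error(nn_stack_dG("ACG"), "dinucleotide")
})

test_that("duplex total = profile sum + corrections (homopolymer arithmetic)", {
  p <- nn_params()
  u22 <- strrep("U", 22)
  expect_equal(duplex_dG_total(u22, p),
               21 * p$stack[["UU"]] + p$init + 2 * p$term_au)
  expect_equal(duplex_dG_total(u22, p, corrections = FALSE),
               21 * p$stack[["UU"]])
  prof <- duplex_dG_profile(u22, p)
  expect_length(prof, 21L)
  expect_true(all(prof == p$stack[["UU"]]))
  expect_error(duplex_dG_total("ACGU"), "length")
  expect_equal(duplex_dG_total("ACGU", expected_length = NULL,
                               corrections = FALSE),
               sum(duplex_dG_profile("ACGU")))
  expect_equal(unname(duplex_dG_profile("GC")), nn_stack_dG("GC"))
})

test_that("profile/total consistency and revcomp symmetry hold over random guides", {
  p <- nn_params()
  guides <- synth_guides(50, seed = 301)
  for (g in guides) {
    prof <- duplex_dG_profile(g, p)
    expect_equal(duplex_dG_total(g, p, corrections = FALSE), sum(prof))
    expect_equal(unname(duplex_dG_profile(rna_revcomp(g), p)),
                 unname(rev(prof)))
  }
  bulk <- mirscan:::duplex_features_bulk(guides, p)
  expect_equal(bulk$dG,
               vapply(guides, duplex_dG_total, numeric(1), params = p,
                      USE.NAMES = FALSE))
  expect_equal(bulk$dG1,
               vapply(guides, function(g) duplex_dG_profile(g, p)[[1L]],
                      numeric(1), USE.NAMES = FALSE))
})

test_that("internal A.U -> G.C substitution never destabilizes the duplex", {
  guides <- synth_guides(25, seed = 302)
  for (g in guides) {
    b <- strsplit(g, "", fixed = TRUE)[[1L]]
    at <- which(b %in% c("A", "U"))
    at <- at[at > 1 & at < 22]
    if (!length(at)) next
    i <- at[[1L]]
    b2 <- b
    b2[i] <- if (b[i] == "A") "G" else "C"
    expect_lte(duplex_dG_total(paste(b2, collapse = "")),
               duplex_dG_total(g))
  }
})

test_that("folding matches exhaustive enumeration on short sequences", {
  p <- nn_params()
  set.seed(303)
  for (i in 1:200) {
    s <- synth_transcript(sample(5:14, 1L))
    f <- fold_self_dG(s, p)
    expect_equal(f$mfe_dG, mfe_oracle(s, p), tolerance = 1e-9)
    expect_lte(f$mfe_dG, 0)
    # the reported structure must itself score the reported energy
    if (f$mfe_dG < 0) {
      expect_equal(structure_energy(s, f$structure, p), f$mfe_dG)
    } else {
      expect_identical(f$structure, strrep(".", nchar(s)))
    }
  }
})

test_that("folding handles designed and degenerate cases", {
  f0 <- fold_self_dG(strrep("A", 10))
  expect_identical(f0$mfe_dG, 0)
  expect_identical(f0$structure, "..........")
  hp <- fold_self_dG("GGGGAAAACCCC")
  expect_lt(hp$mfe_dG, 0)
  # G-run pairs with C-run around the AAAA loop
  expect_match(hp$structure, "^\\(+\\.+\\)+$")
  expect_equal(hp$mfe_dG, mfe_oracle("GGGGAAAACCCC"))
  expect_identical(fold_self_dG("ACGU")$mfe_dG, 0)  # too short to fold
  expect_error(fold_self_dG("ACGT"), "non-ACGU")
})

test_that("dimer energy is symmetric, bounded by the ungapped oracle, and finite", {
  p <- nn_params()
  expect_identical(dimer_dG("AAAA", "AAAA", p), 0)
  set.seed(304)
  for (i in 1:25) {
    a <- synth_transcript(sample(4:8, 1L))
    b <- synth_transcript(sample(4:8, 1L))
    dp <- dimer_dG(a, b, p)
    expect_lte(dp, dimer_ungapped_oracle(a, b, p) + 1e-9)
    expect_lte(dp, 0)
    expect_equal(dimer_dG(b, a, p), dp)
  }
  # palindromic-complement 8-mer forms a full self-duplex
  expect_lt(dimer_dG("GGGGCCCC", "GGGGCCCC", p), 0)
  expect_equal(dimer_dG("ACGU", "ACGU", p),
               dimer_ungapped_oracle("ACGU", "ACGU", p))
})

test_that("target window folding clips at transcript edges", {
  polyA <- strrep("A", 80)
  expect_identical(target_local_dG(polyA, 10), 0)
  tx <- paste0("GGGGAAAACCCC", strrep("A", 40))
  # site at the very start: window is clipped, no error
  expect_equal(target_local_dG(tx, 1, window_flank = 5),
               fold_self_dG(substr(tx, 1, 27))$mfe_dG)
  expect_error(target_local_dG(polyA, 60), "out of transcript bounds")
  # small structured window agrees with enumeration
  w <- "GGGGAAAACCCCAA"
  expect_equal(target_local_dG(paste0(w, strrep("A", 30)), 1,
                               window_flank = 0, site_length = 14),
               mfe_oracle(w))
})

test_that("parameter loading validates invariants", {
  p <- nn_params()
  expect_s3_class(p, "nn_params")
  expect_true(all(diff(p$hairpin) >= 0) && all(p$hairpin > 0))
  expect_gt(p$init, 0)
  # loop penalties extrapolate monotonically past the table
  expect_gt(mirscan:::loop_penalty(p, "hairpin", 40),
            mirscan:::loop_penalty(p, "hairpin", 30))
})
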