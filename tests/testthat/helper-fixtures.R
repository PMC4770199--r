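# shared fixtures: tiny configs and hand-built reads

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 20L, input_picograms = 100, capture_molecules_per_pg = 5,
         pcr_cycles = 2L, seed = 42L),
    list(...))
  do.call(sim_config, args)
}

# geometry where every read reads through into the reverse adapter, so
# collapsing is immune to spurious partial Illumina-adapter trims
readthrough_config <- function(...) {
  tiny_config(fragment_min_bp = 150L, fragment_max_bp = 220L,
              read_length_nt = 300L, ...)
}

SCHEME <- adapter_scheme()
FWD <- SCHEME$forward_malbac
REV <- SCHEME$reverse_malbac

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# assemble a raw read from its parts
build_read <- function(insert, oct5 = "ACGTACGT", oct3 = "TTGGCCAA",
                       offset = "", reverse = TRUE) {
  if (reverse) paste0(offset, FWD, oct5, insert, oct3, REV)
  else paste0(offset, FWD, oct5, insert)
}
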