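# shared fixtures: built in code, tiny, deterministic

canon <- canonical_network()
truth <- load_truth_table()

# archive of zero-error parameter vectors recovered by this package's GA
# (shipped fixture; see ?read_archive)
archive_df <- read_archive()
archive_params <- lapply(seq_len(nrow(archive_df)), function(i) {
  make_params(canon, unlist(archive_df[i, param_names(canon)]))
})

zero_model <- function() feeding_model(canon)

archive_model <- function(i = 1L) feeding_model(canon, archive_params[[i]])

toy_chain2 <- function(w = c(1, 1)) {
  t <- make_toy_chain(2, w)
  feeding_model(t$spec, t$params)
}
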