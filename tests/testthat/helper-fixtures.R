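# Shared desk-sized fixture set, memoized so the suite builds it once per
# seed. Core and stuffer sizes are kept small for speed; the generator's
# scientific defaults are exercised separately in test-fixtures.R.
small_fixture <- local({
  cache <- list()
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      spec <- fixture_spec(seed = seed, core_length_range = c(80L, 250L),
                          stuffer_length = 600L)
      cache[[key]] <<- list(
        spec = spec,
        parts = generate_fixture_parts(spec),
        backbone = generate_fixture_backbone(spec))
    }
    cache[[key]]
  }
})

four_fragment_parts <- function(fx) {
  fx$parts[fx$parts$slot %in% c("pA", "gA", "pB", "gB"), ]
}
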