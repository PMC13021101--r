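# fixtures and their criteria profiles are deterministic; build them once
# per test session
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

get_table2_fixture <- function() memo("t2", table2_fixture)
get_table2_profiles <- function() {
  memo("t2prof", function() evaluate_criteria(get_table2_fixture()))
}
get_table3_fixture <- function() memo("t3", table3_fixture)
get_table3_profiles <- function() {
  memo("t3prof", function() evaluate_criteria(get_table3_fixture()))
}
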