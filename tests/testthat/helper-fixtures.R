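# Hand-checkable toy reaction systems used throughout the suite.
#
# toy1: F = {a, b}; r1: a + b -> ab [c]; r2: a -> c [ab].
#       Neither reaction is a RAF alone (their catalysts are mutual
#       products), but together they sustain each other.
# toy2: F = {a, b}; r1: a + b -> ab [a].  One food-catalysed reaction.
# toy3: toy2 plus r2: ab + b -> abb [ab].  {r1} is a transient RAF whose
#       closure is {r1, r2}; {r2} alone is a co-RAF of {r1}.

toy1 <- function() {
  parse_crs(paste(
    "food: a, b",
    "elements: a, b, ab, c",
    "r1: a + b -> ab [c]",
    "r2: a -> c [ab]",
    sep = "\n"
  ))
}

toy2 <- function() {
  parse_crs(paste(
    "food: a, b",
    "elements: a, b, ab",
    "r1: a + b -> ab [a]",
    sep = "\n"
  ))
}

toy3 <- function() {
  parse_crs(paste(
    "food: a, b",
    "elements: a, b, ab, abb",
    "r1: a + b -> ab [a]",
    "r2: ab + b -> abb [ab]",
    sep = "\n"
  ))
}

# two independent food-catalysed reactions: the canonical decomposable RAF
toy_disjoint <- function() {
  parse_crs(paste(
    "food: a, b",
    "elements: a, b, aa, bb",
    "r1: a -> aa [a]",
    "r2: b -> bb [b]",
    sep = "\n"
  ))
}

# the packaged six-step musician lineage, run end to end
musician_run <- function() {
  tls <- select_through_lines(load_theme_matrix(), 2L, retained = "S")
  run_lineage(build_lineage_fixture(tls, creator = "SLT", audience = "j"))
}
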