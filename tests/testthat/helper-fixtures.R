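# Shared synthetic fixtures, built in code at test time.

# one small planted complex reused by several files
toy_spec <- function(seed = 7) {
  complex_spec(
    chain_lengths = c(30, 30),
    ligand_placements = data.frame(chain = "A", resno = 10, target = 3.0),
    dna_placements = data.frame(chain = "A", resno = 20, target = 3.5),
    partner_chain_placements = data.frame(chain = "B", resno = 15,
                                          target = 4.0),
    core_placements = data.frame(chain = "B", resno = 5),
    seed = seed)
}

toy_entry <- function(seed = 7, dir = tempdir()) {
  path <- file.path(dir, sprintf("toy_%d.pdb", seed))
  tc <- make_toy_complex(toy_spec(seed), path)
  list(entry = parse_structure(path), truth = tc$truth, path = path,
       spec = toy_spec(seed))
}

# independent PDB coordinate reader (fixed-column extraction), used by
# oracle recomputations so they do not share the package's parsing path
read_pdb_atoms_oracle <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    atom = trimws(substr(lines, 13, 16)),
    res = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    stringsAsFactors = FALSE)
}

min_dist_oracle <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(a)))
    best <- min(best, sqrt((a$x[i] - b$x)^2 + (a$y[i] - b$y)^2 +
                             (a$z[i] - b$z)^2))
  best
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("%.6g within %.3g of %.6g", object, tol,
                              expected))
}
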