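# The db2-lite hierarchy format

db2-lite is minidock's documented, line-oriented dialect of a flexibase
hierarchy file: one or more multi-conformer molecules, each carrying the
full topology (atoms, TRIPOS mol2 types, bonds), partial charges, per-atom
desolvation energies, the rigid-component atom list, per-conformer
coordinate blocks and per-conformer builder energies.  It covers the same
content as production flexibase databases but is **not byte-compatible**
with them; content, not byte layout, is the contract here.

Rules:

* Plain text, whitespace-separated tokens.  `#` starts a comment anywhere
  on a line; blank lines are ignored.  Files may be gzipped (`.gz`);
  readers are gzip-transparent.
* Coordinates, charges, desolvation terms and energies are written with 17
  significant digits, so a write/read round trip is lossless.
* Atom and conformer indices are 1-based.
* Every conformer is a complete input conformation.  The rigid-component
  atoms must have identical coordinates in all conformers of a molecule
  (within 1e-3 Angstrom after superposition); readers and writers validate
  this.

## Records

| record | layout | meaning |
|---|---|---|
| header | `db2lite 1` | first non-comment line of the file |
| `M` | `M name natoms nbonds nconformers nrigid` | starts a molecule |
| `A` | `A index name element mol2_type charge vdw_class desolv` | one atom; `charge` in e, `desolv` in kcal/mol |
| `B` | `B from to order` | one bond; `order` is a TRIPOS type (`1`, `2`, `3`, `am`, `ar`) |
| `R` | `R i1 i2 ...` | the rigid-component atom indices (`nrigid` of them; bare `R` if none recorded) |
| `E` | `E e1 e2 ...` | per-conformer energies in kcal/mol (`NA` allowed), `nconformers` values |
| `C` | `C k` | starts conformer `k`; followed by exactly `natoms` lines `x y z` (Angstrom) |

Records appear in the order above; `A` lines are sorted by index and `C`
blocks by conformer number.

## Hand-readable example

A two-atom, one-conformer, one-bond molecule:

```
db2lite 1
# minimal worked example
M TINY 2 1 1 0
A 1 C1 C C.3 0.1 C 0.2
A 2 O2 O O.3 -0.1 O 0.05
B 1 2 1
R
E 0
C 1
0 0 0
1.4 0 0
```

Read it with `read_db2lite("tiny.db2")`; `write_db2lite()` regenerates an
equivalent file.
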