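# Register CSV data dictionary

One row per individual. UTF-8, comma-delimited, header required, no quoting
needed for the tokens below. An empty field means the value is absent; no
sentinel numbers are used.

| column           | type    | unit / tokens                                         | notes |
|------------------|---------|-------------------------------------------------------|-------|
| person_id        | string  | opaque identifier                                     | unique per row |
| sex              | enum    | `F`, `M`                                              | required |
| birth_year       | integer | calendar year                                         | required; the register stores years only, so all ages are whole-year differences |
| education        | enum    | `primary`, `secondary`, `vocational`, `tertiary`, `unknown` | highest completed attainment; `unknown` is a first-class category |
| n_children       | integer | count, >= 0                                           | children ever born that are linked to this individual |
| first_child_year | integer | calendar year                                         | present iff `n_children >= 1`; must exceed `birth_year` |
| last_child_year  | integer | calendar year                                         | present iff `n_children >= 1`; `>= first_child_year`; equals `first_child_year` when `n_children = 1` |
| age_at_death     | integer | whole years, >= 0                                     | absent when unrecorded; the default filters drop individuals with `age_at_death < 15` |

Derived quantities (see `derive_timing()`):

- `afb = first_child_year - birth_year` — age at first birth, whole years.
- `alb = last_child_year - birth_year` — age at last birth, whole years.
- `ibi = (alb - afb) / n_children` — average interbirth interval in years,
  defined only for individuals with at least two children.
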