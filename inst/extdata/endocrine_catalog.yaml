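terms:
- hypothyroidism
- hyperthyroidism
- thyroiditis
- thyrotoxic crisis
- basedow's disease
- hypophysitis
- hypopituitarism
- lymphocytic hypophysitis
- pituitary enlargement
- adrenal insufficiency
- primary adrenocortical insufficiency
- secondary adrenocortical insufficiency
- acute adrenocortical insufficiency
- type 1 diabetes mellitus
- diabetes mellitus
- fulminant type 1 diabetes mellitus
- diabetic ketoacidosis
- diabetes insipidus
- hypoparathyroidism
- hypogonadism
- inappropriate antidiuretic hormone secretion
groups:
  ICI-DM:
  - type 1 diabetes mellitus
  - diabetes mellitus
  - fulminant type 1 diabetes mellitus
  - diabetic ketoacidosis
  thyroid_dysfunction:
  - hypothyroidism
  - hyperthyroidism
  - thyroiditis
  hypophysitis_hypopituitarism:
  - hypophysitis
  - hypopituitarism
  - lymphocytic hypophysitis
  - pituitary enlargement
  adrenal_insufficiency_group:
  - adrenal insufficiency
  - primary adrenocortical insufficiency
  - secondary adrenocortical insufficiency
  - acute adrenocortical insufficiency
  endocrine_all:
  - hypothyroidism
  - hyperthyroidism
  - thyroiditis
  - thyrotoxic crisis
  - basedow's disease
  - hypophysitis
  - hypopituitarism
  - lymphocytic hypophysitis
  - pituitary enlargement
  - adrenal insufficiency
  - primary adrenocortical insufficiency
  - secondary adrenocortical insufficiency
  - acute adrenocortical insufficiency
  - type 1 diabetes mellitus
  - diabetes mellitus
  - fulminant type 1 diabetes mellitus
  - diabetic ketoacidosis
  - diabetes insipidus
  - hypoparathyroidism
  - hypogonadism
  - inappropriate antidiuretic hormone secretion
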