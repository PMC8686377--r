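KIND	COLUMN_ID	SHORT_NAME	LONG_NAME	DATATYPE
patient	OS_STATUS	Overall Survival Status	Overall patient survival status (e.g. 0:LIVING, 1:DECEASED)	STRING
patient	OS_MONTHS	Overall Survival (Months)	Overall survival in months since initial diagnosis	NUMBER
patient	DFS_STATUS	Disease Free Status	Disease free status since initial treatment	STRING
patient	DFS_MONTHS	Disease Free (Months)	Disease free interval in months since initial treatment	NUMBER
patient	AGE	Diagnosis Age	Age at which the condition or disease was first diagnosed, in years	NUMBER
patient	SEX	Sex	Sex of the patient	STRING
patient	CANCER_TYPE	Cancer Type	Cancer type of the patient	STRING
sample	CANCER_TYPE	Cancer Type	Cancer type of the sample	STRING
sample	CANCER_TYPE_DETAILED	Cancer Type Detailed	Detailed cancer type of the sample	STRING
sample	SAMPLE_CLASS	Sample Class	The sample class (e.g. Tumor, cell line, xenograft)	STRING
sample	TUMOR_SIZE	Tumor Size	Tumor size in millimeters	NUMBER
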