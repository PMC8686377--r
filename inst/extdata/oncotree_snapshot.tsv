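CODE	NAME	MAIN_TYPE	PARENT_CODE
tissue	Tissue	Tissue
breast	Breast	Breast Cancer	tissue
brca	Invasive Breast Carcinoma	Breast Cancer	breast
idc	Breast Invasive Ductal Carcinoma	Breast Cancer	brca
ilc	Breast Invasive Lobular Carcinoma	Breast Cancer	brca
lung	Lung	Non-Small Cell Lung Cancer	tissue
nsclc	Non-Small Cell Lung Cancer	Non-Small Cell Lung Cancer	lung
luad	Lung Adenocarcinoma	Non-Small Cell Lung Cancer	nsclc
lusc	Lung Squamous Cell Carcinoma	Non-Small Cell Lung Cancer	nsclc
sclc	Small Cell Lung Cancer	Small Cell Lung Cancer	lung
bowel	Bowel	Colorectal Cancer	tissue
coadread	Colorectal Adenocarcinoma	Colorectal Cancer	bowel
coad	Colon Adenocarcinoma	Colorectal Cancer	coadread
read	Rectal Adenocarcinoma	Colorectal Cancer	coadread
prostate	Prostate	Prostate Cancer	tissue
prad	Prostate Adenocarcinoma	Prostate Cancer	prostate
pancreas	Pancreas	Pancreatic Cancer	tissue
paad	Pancreatic Adenocarcinoma	Pancreatic Cancer	pancreas
skin	Skin	Melanoma	tissue
mel	Melanoma	Melanoma	skin
skcm	Cutaneous Melanoma	Melanoma	mel
brain	CNS/Brain	Glioma	tissue
gb	Glioblastoma	Glioma	brain
ovary	Ovary/Fallopian Tube	Ovarian Cancer	tissue
hgsoc	High-Grade Serous Ovarian Cancer	Ovarian Cancer	ovary
stomach	Esophagus/Stomach	Esophagogastric Cancer	tissue
stad	Stomach Adenocarcinoma	Esophagogastric Cancer	stomach
liver	Liver	Hepatobiliary Cancer	tissue
hcc	Hepatocellular Carcinoma	Hepatobiliary Cancer	liver
kidney	Kidney	Renal Cell Carcinoma	tissue
ccrcc	Renal Clear Cell Carcinoma	Renal Cell Carcinoma	kidney
blood	Blood	Leukemia	tissue
aml	Acute Myeloid Leukemia	Leukemia	blood
all	Acute Lymphoid Leukemia	Leukemia	blood
lymph	Lymphoid	Mature B-Cell Neoplasms	tissue
dlbcl	Diffuse Large B-Cell Lymphoma	Mature B-Cell Neoplasms	lymph
thyroid	Thyroid	Thyroid Cancer	tissue
thpa	Papillary Thyroid Cancer	Thyroid Cancer	thyroid
bladder	Bladder/Urinary Tract	Bladder Cancer	tissue
blca	Bladder Urothelial Carcinoma	Bladder Cancer	bladder
softtissue	Soft Tissue	Soft Tissue Sarcoma	tissue
sarcnos	Sarcoma, NOS	Soft Tissue Sarcoma	softtissue
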