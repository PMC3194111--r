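term,level,outcome,estimate,se,scale
intercept,,attached,1.14,0.03,logodds
intercept,,crawl_space,-0.51,0.04,logodds
intercept,,slab,-0.30,0.04,logodds
intercept,,other_detached,-2.80,0.10,logodds
poverty,below,attached,4.40,,odds_ratio
poverty,below,crawl_space,1.74,,odds_ratio
poverty,below,slab,1.40,,odds_ratio
poverty,below,other_detached,2.36,,odds_ratio
sex,male,attached,0.97,,odds_ratio
sex,male,crawl_space,1.01,,odds_ratio
sex,male,slab,1.00,,odds_ratio
sex,male,other_detached,1.04,,odds_ratio
race,black,attached,2.75,,odds_ratio
race,black,crawl_space,1.46,,odds_ratio
race,black,slab,1.56,,odds_ratio
race,black,other_detached,1.73,,odds_ratio
race,asian,attached,2.34,,odds_ratio
race,asian,crawl_space,0.84,,odds_ratio
race,asian,slab,2.07,,odds_ratio
race,asian,other_detached,2.10,,odds_ratio
race,other,attached,1.76,,odds_ratio
race,other,crawl_space,1.22,,odds_ratio
race,other,slab,1.50,,odds_ratio
race,other,other_detached,2.10,,odds_ratio
race,native,attached,1.91,,odds_ratio
race,native,crawl_space,1.42,,odds_ratio
race,native,slab,1.74,,odds_ratio
race,native,other_detached,1.83,,odds_ratio
region,Northeast,attached,0.44,,odds_ratio
region,Northeast,crawl_space,0.04,,odds_ratio
region,Northeast,slab,0.03,,odds_ratio
region,Northeast,other_detached,0.09,,odds_ratio
region,Midwest,attached,0.21,,odds_ratio
region,Midwest,crawl_space,0.10,,odds_ratio
region,Midwest,slab,0.04,,odds_ratio
region,Midwest,other_detached,0.12,,odds_ratio
region,West,attached,1.35,,odds_ratio
region,West,crawl_space,1.04,,odds_ratio
region,West,slab,1.09,,odds_ratio
region,West,other_detached,0.64,,odds_ratio
age_group,<18,attached,1.11,,odds_ratio
age_group,<18,crawl_space,0.87,,odds_ratio
age_group,<18,slab,1.07,,odds_ratio
age_group,<18,other_detached,0.71,,odds_ratio
age_group,18-24,attached,1.99,,odds_ratio
age_group,18-24,crawl_space,1.01,,odds_ratio
age_group,18-24,slab,1.09,,odds_ratio
age_group,18-24,other_detached,0.91,,odds_ratio
age_group,25-34,attached,2.68,,odds_ratio
age_group,25-34,crawl_space,1.17,,odds_ratio
age_group,25-34,slab,1.31,,odds_ratio
age_group,25-34,other_detached,0.95,,odds_ratio
age_group,35-44,attached,1.25,,odds_ratio
age_group,35-44,crawl_space,0.94,,odds_ratio
age_group,35-44,slab,1.08,,odds_ratio
age_group,35-44,other_detached,0.64,,odds_ratio
age_group,55-64,attached,1.08,,odds_ratio
age_group,55-64,crawl_space,1.08,,odds_ratio
age_group,55-64,slab,1.04,,odds_ratio
age_group,55-64,other_detached,1.26,,odds_ratio
age_group,65-74,attached,1.16,,odds_ratio
age_group,65-74,crawl_space,1.19,,odds_ratio
age_group,65-74,slab,1.10,,odds_ratio
age_group,65-74,other_detached,1.33,,odds_ratio
age_group,75+,attached,1.80,,odds_ratio
age_group,75+,crawl_space,1.39,,odds_ratio
age_group,75+,slab,1.10,,odds_ratio
age_group,75+,other_detached,1.71,,odds_ratio
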